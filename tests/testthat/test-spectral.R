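test_that("SCS+C correction is the identity on flat terrain and recovers
           the closed-form C from noiseless linear data", {
  st <- smallStack(seed = 2)
  flat <- scsCCorrection(st, slopeDeg = 0, aspectDeg = 0,
                         sunZenithDeg = 44.72, C = 0.5)
  expect_equal(flat$stack@values, st@values, tolerance = 1e-12)

  # L = 0.4 cos(i) + 0.1 over a varying slope grid: C = b/m = 0.25
  set.seed(5)
  slope <- matrix(runif(64, 0, 40), 8, 8)
  aspect <- matrix(runif(64, 0, 360), 8, 8)
  theta <- 40 * pi / 180
  cosI <- cos(theta) * cos(slope * pi / 180) +
    sin(theta) * sin(slope * pi / 180) *
      cos(170 * pi / 180 - aspect * pi / 180)
  vals <- array(rep(0.4 * cosI + 0.1, 7), dim = c(8, 8, 7))
  st2 <- new("BandStack", values = vals, layerNames = paste0("B", 1:7),
             origin = c(0, 0), cellSize = 30)
  res <- scsCCorrection(st2, slope, aspect, sunZenithDeg = 40,
                        sunAzimuthDeg = 170)
  expect_equal(unname(res$C), rep(0.25, 7), tolerance = 1e-9)

  # C -> infinity limit: correction factor -> 1
  big <- scsCCorrection(st2, slope, aspect, sunZenithDeg = 40,
                        sunAzimuthDeg = 170, C = 1e9)
  expect_equal(big$stack@values, st2@values, tolerance = 1e-6)
})

test_that("SCS+C preserves the band mean exactly on flat terrain", {
  st <- smallStack(seed = 3)
  out <- scsCCorrection(st, 0, 0, sunZenithDeg = 30)$stack
  for (b in paste0("B", 1:7))
    expect_equal(mean(getLayer(out, b)), mean(getLayer(st, b)),
                 tolerance = 1e-12)
})

test_that("band combinations follow their printed formulas", {
  st <- smallStack(seed = 4)
  v <- st@values
  v[, , 2] <- 0            # B2 = 0 makes MVI5 = 1
  v[, , 7] <- v[, , 5]     # B5 = B7 makes MVI7 = 0
  st2 <- new("BandStack", values = v, layerNames = paste0("B", 1:7),
             origin = c(0, 0), cellSize = 30)
  bc <- bandCombinations(st2)
  expect_true(all(abs(getLayer(bc, "MVI5") - 1) < 1e-12))
  expect_true(all(abs(getLayer(bc, "MVI7")) < 1e-12))
  expect_equal(getLayer(bc, "B76"),
               getLayer(st2, "B7") / getLayer(st2, "B6"),
               tolerance = 1e-12)

  # zero ND563 numerator under the normalized-difference reading
  v[, , 3] <- v[, , 5] + v[, , 6]
  st3 <- new("BandStack", values = v, layerNames = paste0("B", 1:7),
             origin = c(0, 0), cellSize = 30)
  expect_true(all(abs(getLayer(bandCombinations(st3), "ND563")) < 1e-12))
  # literal product variant behind the flag
  prod <- getLayer(bandCombinations(st3, nd563Product = TRUE), "ND563")
  expect_true(all(abs(prod) < 1e-12))
  expect_equal(length(layerNames(bc)), 10)
})

test_that("vegetation indices match hand-evaluated formulas and bounds", {
  st <- smallStack(seed = 6)
  vi <- vegetationIndices(st)
  expect_equal(length(layerNames(vi)), 15)
  B <- lapply(paste0("B", 1:7), function(n) getLayer(st, n))
  names(B) <- paste0("B", 1:7)
  expect_equal(getLayer(vi, "NDVI"),
               (B$B5 - B$B4) / (B$B5 + B$B4), tolerance = 1e-12)
  # scalar EVI oracle at one pixel
  px <- c(2, 3)
  expect_equal(getLayer(vi, "EVI")[px[1], px[2]],
               2.5 * (B$B5[px[1], px[2]] - B$B4[px[1], px[2]]) /
                 (B$B5[px[1], px[2]] + 6 * B$B4[px[1], px[2]] -
                    7.5 * B$B2[px[1], px[2]] + 1), tolerance = 1e-12)
  # NDVI edge cases
  v <- st@values; v[, , 4] <- v[, , 5]
  eq <- new("BandStack", values = v, layerNames = paste0("B", 1:7),
            origin = c(0, 0), cellSize = 30)
  expect_true(all(abs(getLayer(vegetationIndices(eq), "NDVI")) < 1e-12))
  v[, , 4] <- 0
  z4 <- new("BandStack", values = v, layerNames = paste0("B", 1:7),
            origin = c(0, 0), cellSize = 30)
  expect_true(all(getLayer(vegetationIndices(z4), "NDVI") == 1))
  # normalized differences bounded wherever defined
  for (nm in c("NDVI", "GNDVI", "NDMI", "NBR2", "VIG")) {
    x <- getLayer(vi, nm)
    expect_true(all(abs(x[is.finite(x)]) <= 1), info = nm)
  }
})

test_that("GLCM textures match exhaustive pair enumeration", {
  # constant window: one nonzero co-occurrence probability
  const <- matrix(0.5, 5, 5)
  tx <- glcmTexture(const, window = 3, levels = 32)
  expect_equal(tx$Entr[3, 3], 0)
  expect_equal(tx$Hom[3, 3], 1)
  expect_equal(tx$Con[3, 3], 0)
  expect_true(is.na(tx$Entr[1, 1]))  # border

  # 2-level checkerboard, horizontal offset: entropy log 2
  cb <- outer(1:5, 1:5, function(r, c) (r + c) %% 2)
  txc <- glcmTexture(cb, window = 3, levels = 2, directions = 0)
  expect_equal(txc$Entr[3, 3], log(2), tolerance = 1e-12)

  # random windows against the enumeration oracle
  set.seed(9)
  band <- matrix(runif(49), 7, 7)
  offs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  tx2 <- glcmTexture(band, window = 3, levels = 8)
  for (px in list(c(2, 2), c(4, 5), c(6, 3))) {
    w <- band[(px[1] - 1):(px[1] + 1), (px[2] - 1):(px[2] + 1)]
    attr(w, "rng") <- range(band)
    o <- oracleGlcmWindow(w, 8, offs)
    expect_equal(tx2$Entr[px[1], px[2]], o$entropy, tolerance = 1e-12)
    expect_equal(tx2$Con[px[1], px[2]], o$contrast, tolerance = 1e-12)
    expect_equal(tx2$Hom[px[1], px[2]], o$homogeneity, tolerance = 1e-12)
    expect_equal(tx2$SM[px[1], px[2]], o$asm, tolerance = 1e-12)
  }
  expect_error(glcmTexture(matrix(1, 2, 2), window = 3), "window")
})

test_that("GLCM entropy is invariant to grey-level relabelling", {
  set.seed(12)
  levels <- 6
  q <- matrix(sample.int(levels, 49, replace = TRUE), 7, 7)
  perm <- sample.int(levels)
  # map quantized levels through a permutation by spacing band values
  toBand <- function(qq) (qq - 0.5) / levels
  t1 <- glcmTexture(toBand(q), window = 3, levels = levels)
  t2 <- glcmTexture(toBand(matrix(perm[q], 7, 7)), window = 3,
                    levels = levels)
  expect_equal(t1$Entr, t2$Entr, tolerance = 1e-12)
})

test_that("PCA components are ordered, sign-fixed and analytic on toys", {
  # variance only along B5
  vals <- array(0.2, dim = c(6, 6, 7))
  set.seed(4)
  vals[, , 5] <- matrix(runif(36), 6, 6)
  st <- new("BandStack", values = vals, layerNames = paste0("B", 1:7),
            origin = c(0, 0), cellSize = 30)
  res <- suppressWarnings(pcaTransform(st, 1))
  expect_equal(abs(res$loadings["B5", 1]), 1, tolerance = 1e-9)
  expect_gt(res$loadings["B5", 1], 0)  # sign convention
  expect_equal(res$explained[1], 1, tolerance = 1e-9)

  st2 <- smallStack(seed = 20)
  r2 <- pcaTransform(st2, 3)
  expect_true(all(diff(r2$sdev) <= 1e-12))

  # 2-band toy: eigenvalues are the closed-form quadratic roots
  set.seed(7)
  X <- cbind(rnorm(400), rnorm(400))
  X[, 2] <- 0.6 * X[, 1] + 0.4 * X[, 2]
  v2 <- array(c(X[, 1], X[, 2]), dim = c(20, 20, 2))
  stx <- new("BandStack", values = v2, layerNames = c("Ba", "Bb"),
             origin = c(0, 0), cellSize = 30)
  p <- pcaTransform(stx, 2)
  S <- stats::cov(X)
  tr <- S[1, 1] + S[2, 2]; det <- S[1, 1] * S[2, 2] - S[1, 2]^2
  roots <- c((tr + sqrt(tr^2 - 4 * det)) / 2, (tr - sqrt(tr^2 - 4 * det)) / 2)
  expect_equal(p$sdev^2, roots, tolerance = 1e-9)
})

test_that("plot sampling matches the containing pixel and area weights", {
  st <- smallStack(constant = 0.31)
  plots <- data.frame(plot_id = "p1", x = 100, y = 100)
  ctr <- extractPlotFeatures(st, plots, mode = "center")
  area <- extractPlotFeatures(st, plots, mode = "area")
  expect_equal(ctr$B3, 0.31)
  expect_equal(area$B3, 0.31, tolerance = 1e-12)

  # 2-pixel straddle with hand-computed overlap weights
  vals <- array(0, dim = c(1, 2, 1))
  vals[1, 1, 1] <- 10; vals[1, 2, 1] <- 20
  st2 <- new("BandStack", values = vals, layerNames = "F",
             origin = c(0, 0), cellSize = 30)
  # plot 20 m wide centred at x = 28: 12 m in pixel 1, 8 m in pixel 2
  pl <- data.frame(plot_id = "p", x = 28, y = 15)
  out <- extractPlotFeatures(st2, pl, mode = "area", plotWidth = 20,
                             plotHeight = 10)
  expect_equal(out$F, (12 * 10 * 10 + 8 * 10 * 20) / (20 * 10),
               tolerance = 1e-12)
  expect_error(extractPlotFeatures(st2, data.frame(plot_id = "q",
                                                   x = 999, y = 0)),
               "outside")
})

test_that("slope and aspect recover a planar terrain", {
  cs <- 1
  cx <- (1:30 - 0.5) * cs; cy <- (30:1 - 0.5) * cs
  plane <- outer(cy, cx, function(y, x) 40 - 0.2 * x - 0.1 * y)
  dtm <- new("DtmGrid", elevation = plane, origin = c(0, 0), cellSize = cs)
  sa <- slopeAspect(dtm)
  expect_equal(sa$slopeDeg[15, 15], atan(sqrt(0.2^2 + 0.1^2)) * 180 / pi,
               tolerance = 1e-9)
  expect_equal(sa$aspectDeg[15, 15],
               (atan2(0.2, 0.1) * 180 / pi) %% 360, tolerance = 1e-9)
})

test_that("the optical driver yields the documented 91-feature table", {
  sc <- buildScene(sceneConfig(nPlots = 4, seed = 33))
  tab <- sceneOpticalTable(sc)
  expect_equal(nrow(tab), 4)
  expect_equal(ncol(tab), 1 + 91 + 1)  # plot_id + features + response
  expect_false(anyDuplicated(names(tab)) > 0)
  expect_true(all(c("MVI5", "B76", "B65", "B53", "Entr_B5", "ND563",
                    "MVI7", "NDVI", "EVI", "ARVI", "SAVI", "PC1")
                  %in% names(tab)))
})
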
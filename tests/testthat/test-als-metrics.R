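mkCloud <- function(x, y, z, intensity = 100, rn = 1L, cls = "nonground",
                    normalized = TRUE) {
  n <- length(z)
  new("LidarCloud",
      points = data.frame(x = rep_len(x, n), y = rep_len(y, n), z = z,
                          intensity = rep_len(intensity, n),
                          return_number = rep_len(as.integer(rn), n),
                          classification = rep_len(cls, n),
                          stringsAsFactors = FALSE),
      normalized = normalized)
}

test_that("plane-fit noise removal keeps coplanar points, drops outliers", {
  set.seed(1)
  n <- 400
  flat <- mkCloud(runif(n, 0, 5), runif(n, 0, 5), rep(3, n))
  kept <- removeNoise(flat, radius = 1)
  expect_true(all(cloudPoints(kept)$classification == "nonground"))

  # air point 100 m above an exactly flat cloud: the local plane has
  # zero residual spread, so only the outlier exceeds the tie tolerance
  p <- cloudPoints(flat)
  p <- rbind(p, data.frame(x = 2.5, y = 2.5, z = 103, intensity = 100,
                           return_number = 1L,
                           classification = "nonground"))
  noisy <- new("LidarCloud", points = p, normalized = TRUE)
  out <- removeNoise(noisy, radius = 1)
  expect_equal(cloudPoints(out)$classification[n + 1], "noise")
  expect_true(all(cloudPoints(out)$classification[1:n] == "nonground"))
})

test_that("isolated points survive noise removal with a warning", {
  cl <- mkCloud(c(0, 50, 100), c(0, 50, 100), c(1, 2, 3))
  expect_warning(out <- removeNoise(cl, radius = 0.5), "fewer than 3")
  expect_true(all(cloudPoints(out)$classification == "nonground"))
  expect_error(removeNoise(new("LidarCloud")), "empty")
})

test_that("IDW interpolation reproduces constants, exact hits and the
           hand-computed weighted mean", {
  g <- mkCloud(c(0.1, 3.2, 1.7, 2.9), c(0.2, 1.1, 2.8, 0.4), rep(7, 4),
               cls = "ground", normalized = FALSE)
  dtm <- interpolateDtmIdw(g, cellSize = 1)
  expect_true(all(abs(dtm@elevation - 7) < 1e-12))

  # cell center exactly on a ground point takes its elevation
  g2 <- mkCloud(c(0.5, 1.9), c(0.5, 0.7), c(12, 99), cls = "ground",
                normalized = FALSE)
  dtm2 <- interpolateDtmIdw(g2, cellSize = 1)
  expect_equal(dtm2@elevation[nrow(dtm2@elevation), 1], 12)

  # 3-point scalar oracle at a known cell center
  pts <- data.frame(x = c(0.2, 2.6, 1.4), y = c(0.3, 0.8, 2.7),
                    z = c(10, 20, 30))
  dtm3 <- interpolateDtmIdw(pts, cellSize = 3, power = 2, k = 12)
  ctr <- c(1.5, 1.5)
  d <- sqrt((pts$x - ctr[1])^2 + (pts$y - ctr[2])^2)
  w <- d^-2
  expect_equal(dtm3@elevation[1, 1], sum(w * pts$z) / sum(w),
               tolerance = 1e-12)
  expect_error(interpolateDtmIdw(mkCloud(1, 1, 1)), "no ground returns")
})

test_that("height normalization subtracts the bilinear DTM sample", {
  flat <- new("DtmGrid", elevation = matrix(7, 4, 4), origin = c(0, 0),
              cellSize = 1)
  cl <- mkCloud(2, 2, 10, normalized = FALSE)
  expect_equal(cloudPoints(normalizeHeights(cl, flat))$z, 3)
  expect_error(normalizeHeights(mkCloud(99, 2, 10), flat), "outside")

  # sloped plane: bilinear interpolation of a linear surface is exact,
  # so each point matches the per-point plane oracle
  cs <- 0.5
  nr <- 20; nc <- 20
  cx <- (seq_len(nc) - 0.5) * cs
  cy <- (nr - seq_len(nr) + 0.5) * cs
  plane <- function(x, y) 50 + 0.3 * x - 0.1 * y
  dtm <- new("DtmGrid", elevation = outer(cy, cx, function(y, x)
    plane(x, y)), origin = c(0, 0), cellSize = cs)
  set.seed(4)
  x <- runif(50, 1, 9); y <- runif(50, 1, 9); h <- runif(50, 0, 20)
  cl2 <- mkCloud(x, y, plane(x, y) + h, normalized = FALSE)
  expect_equal(cloudPoints(normalizeHeights(cl2, dtm))$z, h,
               tolerance = 1e-9)
})

test_that("ground returns normalize to near zero within a synthetic plot", {
  cfg <- sceneConfig(nPlots = 1, seed = 6, slopeDeg = 5)
  cl <- simulatePointCloud(cfg, agb = 90, center = c(45, 45),
                           plotIndex = 1)
  norm <- normalizeHeights(cl, interpolateDtmIdw(cl))
  gz <- cloudPoints(norm)$z[cloudPoints(norm)$classification == "ground"]
  expect_lt(stats::quantile(abs(gz), 0.95), 0.6)
})

test_that("elevation metrics match direct statistics and the sort oracle", {
  cl <- mkCloud(0, 0, c(3, 4, 5))
  m <- elevationMetrics(cl)
  expect_equal(unname(m["elev_mean"]), 4)
  expect_equal(unname(elevationMetrics(mkCloud(0, 0, rep(6, 5)))["elev_cv"]),
               0)
  set.seed(10)
  z <- runif(1000, 2, 40)
  m2 <- elevationMetrics(mkCloud(0, 0, z))
  for (p in c(1, 5, 60, 95, 99))
    expect_equal(unname(m2[paste0("elev_per_", p, "th")]),
                 oraclePercentile(z, p), tolerance = 1e-12)
  expect_warning(elevationMetrics(mkCloud(0, 0, c(0.5, 1))), "NaN")
})

test_that("density deciles partition above-threshold returns", {
  # degenerate span: every return at the threshold height
  flat <- densityMetrics(mkCloud(0, 0, rep(2, 50)))
  expect_equal(unname(flat), c(1, rep(0, 9)))
  # everything except one top return in the lowest slice
  low <- densityMetrics(mkCloud(0, 0, c(rep(2.1, 49), 10)))
  expect_equal(unname(low), c(0.98, rep(0, 8), 0.02))
  set.seed(2)
  z <- runif(500, 0, 35)
  d2 <- densityMetrics(mkCloud(0, 0, z))
  expect_equal(sum(d2), 1, tolerance = 1e-12)
  expect_equal(unname(d2), oracleDensity(z), tolerance = 1e-12)
  # binomial check on uniform heights
  z3 <- runif(10000, 2, 22)
  d3 <- densityMetrics(mkCloud(0, 0, z3))
  expect_true(all(abs(d3 - 0.1) < 3 * sqrt(0.1 * 0.9 / 10000) + 1e-3))
})

test_that("intensity metrics and AII match the brute-force oracles", {
  m <- intensityMetrics(mkCloud(0, 0, c(5, 9), intensity = c(10, 20)))
  expect_equal(unname(m["int_max"]), 20)
  m2 <- intensityMetrics(mkCloud(0, 0, c(4, 8), intensity = c(30, 30)))
  expect_equal(unname(m2["int_AII_50th"]), 0.5)
  set.seed(7)
  z <- runif(800, 2, 30); i <- runif(800, 0, 300)
  m3 <- intensityMetrics(mkCloud(0, 0, z, intensity = i))
  for (k in c(1, 40, 75, 99))
    expect_equal(unname(m3[paste0("int_AII_", k, "th")]),
                 oracleAii(z, i, k), tolerance = 1e-12)
  expect_equal(unname(m3["int_AII_99th"]) <= 1, TRUE)
  expect_warning(intensityMetrics(mkCloud(0, 0, c(3, 4), intensity = 0)),
                 "AII")
})

test_that("forest metrics follow their defining ratios", {
  z <- c(runif(30, 0, 1.9), runif(70, 2.1, 25))
  cl <- mkCloud(0, 0, z)
  fm <- forestMetrics(cl)
  expect_equal(unname(fm["gap_fraction"]), 0.3)
  expect_equal(unname(fm["canopy_cover"]), 0.7)
  expect_equal(unname(fm["lai"]), -log(0.3) / 0.5)
  allHigh <- mkCloud(0, 0, runif(50, 3, 20))
  expect_equal(unname(suppressWarnings(forestMetrics(allHigh))["canopy_cover"]), 1)
  expect_warning(fm2 <- forestMetrics(allHigh), "gap fraction 0")
  expect_true(is.nan(fm2[["lai"]]))
  # gap fraction and the above-threshold fraction partition the returns
  expect_equal(unname(fm["gap_fraction"]) + mean(z >= 2), 1)
})

test_that("metric extraction is order-invariant with a stable header", {
  cfg <- sceneConfig(nPlots = 4, seed = 13)
  sc <- buildScene(cfg)
  clouds <- lapply(sc$clouds, function(cl) {
    p <- cloudPoints(cl); p$z <- p$z - 100
    new("LidarCloud", points = p, normalized = TRUE)
  })
  t1 <- extractAlsMetrics(clouds)
  t2 <- extractAlsMetrics(rev(clouds))
  expect_identical(t1, t2)
  t0 <- extractAlsMetrics(list())
  expect_equal(nrow(t0), 0)
  expect_identical(names(t0), names(t1))
})

test_that("metrics are invariant to a vertical datum shift", {
  cfg <- sceneConfig(nPlots = 1, seed = 19)
  cl <- simulatePointCloud(cfg, agb = 110, plotIndex = 1)
  shift <- function(cl, c) {
    p <- cloudPoints(cl); p$z <- p$z + c
    new("LidarCloud", points = p, normalized = FALSE)
  }
  mA <- elevationMetrics(normalizeHeights(cl, interpolateDtmIdw(cl)))
  clB <- shift(cl, 55.5)
  mB <- elevationMetrics(normalizeHeights(clB, interpolateDtmIdw(clB)))
  expect_equal(mA, mB, tolerance = 1e-9)
})

test_that("the simple ground classifier labels a flat floor", {
  set.seed(3)
  n <- 500
  cl <- mkCloud(runif(n, 0, 30), runif(n, 0, 30),
                c(rep(0, 200), runif(n - 200, 5, 20)) + rnorm(n, 0, 0.05),
                normalized = FALSE)
  out <- classifyGroundSimple(cl)
  cls <- cloudPoints(out)$classification
  expect_true(mean(cls[1:200] == "ground") > 0.95)
  expect_true(mean(cls[201:n] == "nonground") > 0.95)
})
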
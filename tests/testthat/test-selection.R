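test_that("Pearson filter keeps perfect copies, drops constants, and
           matches the t-distribution oracle", {
  set.seed(1)
  n <- 20
  y <- rnorm(n, 100, 30)
  # construct a feature with sample correlation exactly 0.3
  e <- rnorm(n)
  eo <- residuals(lm(e ~ y))
  x03 <- 0.3 * as.vector(scale(y)) + sqrt(1 - 0.09) * as.vector(scale(eo))
  tab <- data.frame(copy = y, const = 5, weak = x03, agb = y)
  res <- pearsonFilter(tab)
  expect_true(res$pass[res$feature == "copy"])
  expect_equal(res$r[res$feature == "copy"], 1, tolerance = 1e-12)
  expect_false(res$pass[res$feature == "const"])
  expect_true(is.na(res$r[res$feature == "const"]))
  # oracle: p = 2 * S_t(|t|, n-2), t = r sqrt(n-2) / sqrt(1-r^2)
  r <- res$r[res$feature == "weak"]
  expect_equal(r, 0.3, tolerance = 1e-9)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(res$p[res$feature == "weak"],
               2 * pt(abs(tstat), n - 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_false(res$pass[res$feature == "weak"])
})

test_that("random-forest ranking puts the informative feature first and
           is seed-deterministic", {
  set.seed(2)
  n <- 60
  x <- runif(n)
  tab <- data.frame(x = x, n1 = runif(n), n2 = runif(n), n3 = runif(n),
                    agb = x)
  rk <- rfImportanceRanking(tab, c("x", "n1", "n2", "n3"), nRuns = 10,
                            nTrees = 100)
  expect_gte(sum(rk$ranks[, "x"] == 1), 9)
  rk2 <- rfImportanceRanking(tab, c("x", "n1", "n2", "n3"), nRuns = 10,
                             nTrees = 100)
  expect_identical(rk$ranks, rk2$ranks)
  expect_error(rfImportanceRanking(data.frame(a = 1:5, agb = rep(1, 5)),
                                   "a"), "degenerate")
})

test_that("stable-top selection sorts by mean rank with declared ties", {
  mr <- c(f1 = 2, f2 = 1, f3 = 2, f4 = 5)
  r <- c(f1 = 0.2, f2 = 0.9, f3 = -0.8, f4 = 0.1)
  expect_identical(selectStableTop(mr, r, k = 3), c("f2", "f3", "f1"))
  expect_warning(out <- selectStableTop(mr, r, k = 9), "returning all")
  expect_length(out, 4)
})

test_that("best LiDAR variable is the highest univariate R-squared", {
  set.seed(3)
  n <- 50
  y <- rnorm(n, 150, 40)
  e <- as.vector(scale(residuals(lm(rnorm(n) ~ y))))
  mk <- function(r) r * as.vector(scale(y)) + sqrt(1 - r^2) * e
  tab <- data.frame(strong = mk(0.9), weakf = mk(0.1), agb = y)
  res <- bestLidarVariable(tab)
  expect_equal(res$best, "strong")
  # univariate OLS: R^2 = r^2
  expect_equal(res$report$r2[res$report$feature == "strong"], 0.81,
               tolerance = 1e-9)
  perfect <- data.frame(lin = 3 * y - 7, agb = y)
  pr <- bestLidarVariable(perfect)
  expect_equal(pr$report$r2[1], 1, tolerance = 1e-12)
})

test_that("COLI formulas match their element-wise oracles", {
  set.seed(4)
  tab <- data.frame(plot_id = letters[1:10], sf1 = runif(10, -1, 1),
                    sf2 = runif(10, 0.1, 2), blv = runif(10, 1, 20),
                    agb = runif(10, 10, 200))
  c1 <- computeColi1(tab, c("sf1", "sf2"), "blv")
  expect_equal(c1$COLI1_sf1, tab$sf1 * tab$blv, tolerance = 1e-15)
  c2 <- computeColi2(tab, c("sf1", "sf2"), "blv")
  expect_equal(c2$COLI2_sf2, (tab$blv - tab$sf2) / (tab$blv + tab$sf2),
               tolerance = 1e-15)
  # scalar cases
  one <- data.frame(sf = 2, blv = 3)
  expect_equal(computeColi1(one, "sf", "blv")$COLI1_sf, 6)
  expect_equal(computeColi1(data.frame(sf = 0, blv = 3), "sf",
                            "blv")$COLI1_sf, 0)
  expect_equal(computeColi2(data.frame(sf = 3, blv = 3), "sf",
                            "blv")$COLI2_sf, 0)
  expect_equal(computeColi2(data.frame(sf = 0, blv = 3), "sf",
                            "blv")$COLI2_sf, 1)
  expect_warning(z <- computeColi2(data.frame(sf = -3, blv = 3), "sf",
                                   "blv"), "zero denominator")
  expect_true(is.nan(z$COLI2_sf))
  expect_error(computeColi1(one, "missing_col", "blv"), "missing_col")
  # bounded in (-1, 1) for positive inputs
  expect_true(all(abs(c2$COLI2_sf2) < 1))
})

test_that("COLI scaling behaves under a positive rescale of the BLV", {
  set.seed(5)
  tab <- data.frame(sf = runif(20, 0.1, 2), blv = runif(20, 1, 10))
  a <- computeColi1(tab, "sf", "blv")$COLI1_sf
  tab2 <- tab; tab2$blv <- 3 * tab$blv; tab2$sf <- 3 * tab$sf
  b1 <- computeColi1(within(tab, blv <- 3 * blv), "sf", "blv")$COLI1_sf
  expect_equal(b1, 3 * a, tolerance = 1e-12)
  s1 <- sign(computeColi2(tab, "sf", "blv")$COLI2_sf)
  s2 <- sign(computeColi2(tab2, "sf", "blv")$COLI2_sf)
  expect_identical(s1, s2)
})

test_that("experiment sets assemble with the designed column counts", {
  alsSel <- paste0("als", 1:9)
  optSel <- paste0("opt", 1:9)
  set.seed(6)
  tab <- as.data.frame(matrix(runif(20 * 18), 20,
                              dimnames = list(NULL, c(alsSel, optSel))))
  tab$plot_id <- sprintf("p%02d", 1:20)
  tab$agb <- runif(20, 20, 200)
  tab <- computeColi1(tab, optSel, "als1")
  tab <- computeColi2(tab, optSel, "als1")
  want <- c("F1" = 9, "F2" = 9, "F1+2" = 18, "F4" = 9, "F5" = 9,
            "F2+3" = 10, "F1+2+4" = 27, "F1+2+5" = 27)
  for (id in names(want)) {
    out <- assembleExperiment(tab, id, alsSel, optSel, "als1")
    expect_equal(ncol(out) - 2, unname(want[id]), info = id)
    expect_false(anyDuplicated(names(out)) > 0, info = id)
  }
  expect_error(assembleExperiment(tab, "F9", alsSel, optSel, "als1"),
               "valid")
})

test_that("the selection pipeline is a pure function of table and seeds", {
  set.seed(7)
  n <- 40
  y <- runif(n, 50, 250)
  tab <- data.frame(a = y + rnorm(n, 0, 10), b = y + rnorm(n, 0, 40),
                    c = rnorm(n), d = sqrt(y) + rnorm(n, 0, 1),
                    e = rnorm(n), agb = y)
  s1 <- selectFeatures(tab, k = 3, nTrees = 100)
  s2 <- selectFeatures(tab, k = 3, nTrees = 100)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$ranking$ranks, s2$ranking$ranks)
  expect_true(all(s1$selected %in%
                    s1$pearson$feature[s1$pearson$pass]))
})
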
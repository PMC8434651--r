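# Model evaluation: the six-headline-metric suite over actual/predicted
# AGB pairs, the leave-one-out cross-validation harness (base and stacked
# models under the same no-leakage contract), the experiment-grid runner,
# wall-to-wall raster prediction and histogram comparison.

#' Evaluation metric suite
#'
#' Over n actual/predicted pairs (y, yhat) with ybar = mean(y):
#' RMSE = sqrt(mean((y - yhat)^2)); rRMSE = RMSE / ybar;
#' MAE = mean(|y - yhat|); MAPE = 100 * mean(|y - yhat| / y);
#' PM = sum((y - yhat)^2) / sum((y - ybar)^2);
#' R^2 = squared Pearson correlation of y and yhat. The unbounded
#' regression-sum-of-squares variant sum((yhat - ybar)^2) /
#' sum((y - ybar)^2) is reported alongside as `eq5_r2` (it exceeds 1 for
#' biased predictions, so it is not the headline figure).
#'
#' MAPE is NaN with a warning when any y is 0; R^2, eq5_r2 and PM are
#' NaN with a warning when y has zero variance.
#'
#' @param actual,predicted numeric vectors (n >= 2), aligned.
#' @return named list: `r2`, `eq5_r2`, `rmse`, `rrmse`, `mae`, `mape`,
#'   `pm`, `n`.
#' @examples
#' metricsSuite(c(100, 200, 300), c(110, 190, 330))
#' @export
metricsSuite <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  ok <- is.finite(actual) & is.finite(predicted)
  y <- actual[ok]; yh <- predicted[ok]
  n <- length(y)
  if (n < 2) stop("need at least 2 complete pairs")
  ybar <- mean(y)
  rmse <- sqrt(mean((y - yh)^2))
  mae <- mean(abs(y - yh))
  mape <- if (any(y == 0)) {
    warning("actual value 0; MAPE undefined, reported NaN")
    NaN
  } else 100 * mean(abs(y - yh) / y)
  sst <- sum((y - ybar)^2)
  if (sst == 0) {
    warning("zero variance in actuals; R^2 and PM undefined")
    r2 <- eq5 <- pm <- NaN
  } else {
    pm <- sum((y - yh)^2) / sst
    eq5 <- sum((yh - ybar)^2) / sst
    r2 <- if (stats::sd(yh) == 0) NaN else stats::cor(y, yh)^2
  }
  list(r2 = r2, eq5_r2 = eq5, rmse = rmse, rrmse = rmse / ybar, mae = mae,
       mape = mape, pm = pm, n = n)
}

.isStackSpec <- function(spec) inherits(spec, "agb_stack_spec")

.fitAny <- function(spec, X, y, budget) {
  if (.isStackSpec(spec)) fitStack(spec, X, y, budget)
  else fitModel(.applyBudget(spec, budget), X, y)
}

#' Leave-one-out cross-validation of a base or stacked model
#'
#' Each plot is predicted by a model trained on the other n - 1 plots;
#' per-fold seeds derive deterministically from the master seed (seed +
#' fold index), so the run is exactly reproducible. A failing fold
#' records an NA prediction with a warning and the metrics cover the
#' completed folds.
#'
#' @param spec a [modelSpec()] or [stackSpec()].
#' @param table feature table with `plot_id` (optional), feature columns
#'   and the response.
#' @param response response column name, default `"agb"`.
#' @param budget budget profile name or list.
#' @param masterSeed master seed; default the spec's own.
#' @return list: `pairs` (data.frame plot_id, actual, predicted),
#'   `report` (from [metricsSuite()]), `coverage` (fraction of completed
#'   folds).
#' @export
loocvEvaluate <- function(spec, table, response = "agb", budget = "full",
                          masterSeed = spec$seed) {
  ids <- if ("plot_id" %in% names(table)) table$plot_id
         else as.character(seq_len(nrow(table)))
  feats <- setdiff(names(table), c("plot_id", response))
  X <- table[, feats, drop = FALSE]
  y <- table[[response]]
  n <- nrow(X)
  if (n < 3) stop("LOOCV needs at least 3 rows")
  pred <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    si <- .withSeed(spec, masterSeed + i)
    pred[i] <- tryCatch(
      predict(.fitAny(si, X[-i, , drop = FALSE], y[-i], budget),
              X[i, , drop = FALSE]),
      error = function(e) {
        warning("fold ", i, " failed: ", conditionMessage(e))
        NA_real_
      })
  }
  pairs <- data.frame(plot_id = ids, actual = y, predicted = pred,
                      stringsAsFactors = FALSE)
  list(pairs = pairs, report = metricsSuite(y, pred),
       coverage = mean(!is.na(pred)))
}

#' Run an experiment grid
#'
#' Evaluates every combination of feature set and algorithm by LOOCV and
#' returns one tidy row per cell (Features, Algorithm, R^2, RMSE, rRMSE,
#' MAE, MAPE, PM). Algorithm labels `"SG(<meta>)"` denote stacked
#' generalization with the default base set RF + SVR + KNN + CNN and the
#' named meta model. Failed cells carry NaN metrics.
#'
#' @param featureSets named list of feature tables (each with the
#'   response column).
#' @param algorithms character vector of base algorithm names and/or
#'   `"SG(RF)"`, `"SG(SVR)"`, `"SG(KNN)"`, `"SG(CNN)"`.
#' @param response response column name.
#' @param masterSeed master seed; each cell derives its own stream.
#' @param budget budget profile name or list.
#' @return data.frame of evaluation rows.
#' @export
runExperiments <- function(featureSets, algorithms, response = "agb",
                           masterSeed = 10L, budget = "full") {
  cells <- expand.grid(features = names(featureSets),
                       algorithm = algorithms, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    fs <- cells$features[ci]; alg <- cells$algorithm[ci]
    cellSeed <- as.integer((masterSeed + 7700 * ci) %% 2147480000)
    spec <- if (grepl("^SG\\(", alg)) {
      meta <- sub("^SG\\((.*)\\)$", "\\1", alg)
      stackSpec(metaSpec = modelSpec(meta), seed = cellSeed,
                innerK = if (is.character(budget))
                  budgetProfile(budget)$innerK else budget$innerK)
    } else modelSpec(alg, seed = cellSeed)
    rep <- tryCatch(
      loocvEvaluate(spec, featureSets[[fs]], response, budget,
                    masterSeed = cellSeed)$report,
      error = function(e) {
        warning("cell ", fs, " / ", alg, " failed: ",
                conditionMessage(e))
        list(r2 = NaN, rmse = NaN, rrmse = NaN, mae = NaN, mape = NaN,
             pm = NaN)
      })
    data.frame(features = fs, algorithm = alg, r2 = rep$r2,
               rmse = rep$rmse, rrmse = rep$rrmse, mae = rep$mae,
               mape = rep$mape, pm = rep$pm, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Wall-to-wall AGB prediction over feature rasters
#'
#' Builds the per-pixel feature vector from the named layers, predicts
#' with a fitted base or stacked model, masks pixels with any missing
#' layer value, clips negative predictions to 0 (declared rule) and
#' attaches summary statistics.
#'
#' @param model an [AgbModel-class] or [AgbStackModel-class].
#' @param stack a [BandStack-class] containing every model feature as a
#'   layer.
#' @return a [PredictionMap-class].
#' @export
wallToWallPredict <- function(model, stack) {
  feats <- if (is(model, "AgbStackModel"))
    model@baseModels[[1]]@featureNames else model@featureNames
  miss <- setdiff(feats, layerNames(stack))
  if (length(miss))
    stop("missing feature layer(s): ", paste(miss, collapse = ", "))
  d <- dim(stack@values)
  X <- vapply(feats, function(f) as.vector(getLayer(stack, f)),
              numeric(d[1] * d[2]))
  ok <- stats::complete.cases(X)
  agb <- rep(NA_real_, d[1] * d[2])
  if (any(ok)) {
    p <- predict(model, as.data.frame(X[ok, , drop = FALSE]))
    agb[ok] <- pmax(0, p)
  }
  m <- matrix(agb, d[1], d[2])
  v <- agb[!is.na(agb)]
  new("PredictionMap", agb = m, origin = stack@origin,
      cellSize = stack@cellSize,
      summary = c(min = min(v), max = max(v), mean = mean(v),
                  sd = stats::sd(v)))
}

#' Compare map and plot AGB distributions
#'
#' Aligned relative-frequency histograms with half-open bins
#' [lo, hi) of the given width, covering the pooled range; the last bin
#' is closed above.
#'
#' @param mapValues numeric vector (e.g. non-NA pixels of a
#'   [PredictionMap-class]).
#' @param plotValues numeric vector of plot AGB.
#' @param binWidth bin width in Mg/ha, default 50.
#' @return data.frame `bin_lo`, `bin_hi`, `freq_map`, `freq_plots`,
#'   `diff`.
#' @export
histogramCompare <- function(mapValues, plotValues, binWidth = 50) {
  mapValues <- mapValues[is.finite(mapValues)]
  plotValues <- plotValues[is.finite(plotValues)]
  if (!length(mapValues) || !length(plotValues)) stop("empty input")
  lo <- floor(min(mapValues, plotValues) / binWidth) * binWidth
  hi <- max(mapValues, plotValues)
  breaks <- seq(lo, lo + binWidth * ceiling((hi - lo) / binWidth + 1e-12),
                by = binWidth)
  if (breaks[length(breaks)] <= hi) breaks <- c(breaks, breaks[length(breaks)] + binWidth)
  binOf <- function(v) pmin(floor((v - lo) / binWidth) + 1,
                            length(breaks) - 1)
  fm <- tabulate(binOf(mapValues), length(breaks) - 1) / length(mapValues)
  fp <- tabulate(binOf(plotValues), length(breaks) - 1) /
    length(plotValues)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             freq_map = fm, freq_plots = fp, diff = fm - fp)
}
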
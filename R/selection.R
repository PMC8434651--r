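# Two-step feature selection (Pearson significance filter, then repeated
# random-forest importance ranking), identification of the best
# LiDAR variable by univariate regression, COLI optical-LiDAR fusion
# features, and assembly of the experiment feature sets.

#' Pearson correlation filter
#'
#' Correlates every feature with the response; two-sided p-values come
#' from the t transform t = r * sqrt(n - 2) / sqrt(1 - r^2) with n - 2
#' degrees of freedom. Features with p below `alpha` pass. Zero-variance
#' features have undefined r and are excluded (recorded with NA).
#'
#' @param table feature table: numeric feature columns plus the response.
#' @param response response column name, default `"agb"`.
#' @param alpha significance level, default 0.05.
#' @return data.frame `feature`, `r`, `p`, `pass`.
#' @export
pearsonFilter <- function(table, response = "agb", alpha = 0.05) {
  feats <- setdiff(names(table)[vapply(table, is.numeric, TRUE)], response)
  y <- table[[response]]
  rows <- lapply(feats, function(f) {
    x <- table[[f]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(feature = f, r = NA_real_, p = NA_real_,
                        pass = FALSE, stringsAsFactors = FALSE))
    r <- stats::cor(x[ok], y[ok])
    p <- if (abs(r) >= 1) 0 else {
      t <- r * sqrt(n - 2) / sqrt(1 - r^2)
      2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
    }
    data.frame(feature = f, r = r, p = p, pass = p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Repeated random-forest importance ranking
#'
#' Fits a random-forest regressor `nRuns` times with the given seeds and
#' ranks features by impurity-based importance (rank 1 = most important)
#' within each run; the mean rank across runs is the stability score.
#'
#' @param table feature table including the response.
#' @param features feature names to rank (at least 1).
#' @param response response column name.
#' @param nRuns number of repetitions, default 10.
#' @param seeds one seed per run, default 0..nRuns-1.
#' @param nTrees trees per forest, default 1000.
#' @return list: `ranks` (nRuns x features matrix), `meanRank` (named,
#'   ascending order is better).
#' @export
rfImportanceRanking <- function(table, features, response = "agb",
                                nRuns = 10, seeds = seq_len(nRuns) - 1,
                                nTrees = 1000) {
  if (length(features) < 1) stop("need at least one feature")
  y <- table[[response]]
  if (stats::sd(y) == 0) stop("degenerate (constant) response")
  X <- table[, features, drop = FALSE]
  ranks <- matrix(NA_real_, nRuns, length(features),
                  dimnames = list(NULL, features))
  for (i in seq_len(nRuns)) {
    set.seed(seeds[i])
    rf <- randomForest::randomForest(x = X, y = y, ntree = nTrees)
    imp <- rf$importance[, 1]
    ranks[i, ] <- rank(-imp, ties.method = "average")
  }
  list(ranks = ranks, meanRank = colMeans(ranks))
}

#' Select the most stable top-ranked features
#'
#' Sorts by mean rank ascending; ties are broken by |r| descending, then
#' by name. When fewer than `k` features are available the whole pool is
#' returned with a warning.
#'
#' @param meanRank named mean ranks (smaller = better).
#' @param r named Pearson correlations used for tie-breaking (optional).
#' @param k number of features to keep, default 9.
#' @return character vector of selected feature names, best first.
#' @export
selectStableTop <- function(meanRank, r = NULL, k = 9) {
  nm <- names(meanRank)
  absR <- if (is.null(r)) rep(0, length(nm)) else abs(r[nm])
  absR[is.na(absR)] <- 0
  ord <- order(meanRank, -absR, nm)
  if (length(nm) < k) {
    warning("only ", length(nm), " features available; returning all")
    k <- length(nm)
  }
  nm[ord][seq_len(k)]
}

#' Two-step feature selection
#'
#' Convenience wrapper: Pearson filter at `alpha`, then repeated
#' random-forest importance ranking of the passing features, then the
#' stable top-k.
#'
#' @inheritParams pearsonFilter
#' @inheritParams rfImportanceRanking
#' @param k features to keep, default 9.
#' @return list: `selected` (ordered names), `pearson` (filter table),
#'   `ranking` (from [rfImportanceRanking()]).
#' @export
selectFeatures <- function(table, response = "agb", alpha = 0.05, k = 9,
                           nRuns = 10, seeds = seq_len(nRuns) - 1,
                           nTrees = 1000) {
  pe <- pearsonFilter(table, response, alpha)
  pool <- pe$feature[pe$pass]
  if (length(pool) == 0) stop("no feature passed the Pearson filter")
  if (length(pool) == 1)
    return(list(selected = pool, pearson = pe,
                ranking = list(ranks = NULL,
                               meanRank = setNames(1, pool))))
  rk <- rfImportanceRanking(table, pool, response, nRuns, seeds, nTrees)
  sel <- selectStableTop(rk$meanRank, setNames(pe$r, pe$feature), k)
  list(selected = sel, pearson = pe, ranking = rk)
}

#' Best-performing LiDAR variable by univariate regression
#'
#' Fits an ordinary least-squares regression of the response on each ALS
#' feature alone and reports the six evaluation metrics of
#' [metricsSuite()] per candidate; the feature with the highest R^2 wins
#' (ties to 1e-12 go to the first by column order, with a message).
#'
#' @param table ALS feature table including the response.
#' @param features candidate feature names (default: all numeric columns
#'   except the response).
#' @param response response column name.
#' @return list: `best` (feature name), `report` (data.frame of per-
#'   feature metrics, sorted by R^2 descending).
#' @export
bestLidarVariable <- function(table, features = NULL, response = "agb") {
  if (is.null(features))
    features <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                        response)
  if (length(features) < 1) stop("need at least one candidate feature")
  y <- table[[response]]
  rows <- lapply(features, function(f) {
    x <- table[[f]]
    if (!all(is.finite(x)) || stats::sd(x) == 0) return(NULL)
    fit <- stats::lm(y ~ x)
    m <- metricsSuite(y, stats::fitted(fit))
    cbind(data.frame(feature = f, stringsAsFactors = FALSE),
          as.data.frame(m[c("r2", "rmse", "rrmse", "mae", "mape", "pm")]))
  })
  rep <- do.call(rbind, rows)
  if (is.null(rep)) stop("all univariate fits degenerate")
  best <- rep$feature[rep$r2 >= max(rep$r2) - 1e-12][1]
  if (sum(rep$r2 >= max(rep$r2) - 1e-12) > 1)
    message("R^2 tie; keeping first feature by column order: ", best)
  list(best = best, report = rep[order(-rep$r2), , drop = FALSE])
}

.requireCols <- function(table, cols) {
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
}

#' COLI1 fusion features (product form)
#'
#' Adds one column per selected optical feature SF: COLI1_SF = SF * BLV,
#' where BLV is the best-performing LiDAR variable.
#'
#' @param table feature table containing `blv` and all `sf` columns.
#' @param sf names of the selected optical features.
#' @param blv name of the best LiDAR variable column.
#' @return the table with `COLI1_<sf>` columns appended.
#' @export
computeColi1 <- function(table, sf, blv) {
  .requireCols(table, c(sf, blv))
  for (f in sf) table[[paste0("COLI1_", f)]] <- table[[f]] * table[[blv]]
  table
}

#' COLI2 fusion features (normalized-difference form)
#'
#' Adds COLI2_SF = (BLV - SF) / (BLV + SF) per selected optical feature.
#' Denominators with |BLV + SF| < 1e-12 yield NaN with a warning.
#'
#' @inheritParams computeColi1
#' @return the table with `COLI2_<sf>` columns appended.
#' @export
computeColi2 <- function(table, sf, blv) {
  .requireCols(table, c(sf, blv))
  nBad <- 0L
  for (f in sf) {
    den <- table[[blv]] + table[[f]]
    v <- (table[[blv]] - table[[f]]) / den
    bad <- abs(den) < 1e-12
    v[bad] <- NaN
    nBad <- nBad + sum(bad)
    table[[paste0("COLI2_", f)]] <- v
  }
  if (nBad > 0) warning(nBad, " COLI2 value(s) NaN on zero denominators")
  table
}

#' Assemble an experiment feature set
#'
#' Builds the eight designed feature sets from the selected ALS features
#' (F1, 9), the selected optical features (F2, 9), the best LiDAR
#' variable (F3, 1), all COLI1 (F4, 9) and all COLI2 (F5, 9):
#' `"F1"`, `"F2"`, `"F1+2"` (18), `"F4"`, `"F5"`, `"F2+3"` (10),
#' `"F1+2+4"` (27), `"F1+2+5"` (27).
#'
#' @param table merged feature table containing every needed column plus
#'   the response.
#' @param id experiment feature-set id (see above).
#' @param alsSel,optSel ordered selected ALS / optical feature names.
#' @param blv best LiDAR variable column name.
#' @param response response column name.
#' @return data.frame: `plot_id` (if present), the set's feature columns
#'   and the response.
#' @export
assembleExperiment <- function(table, id, alsSel, optSel, blv,
                               response = "agb") {
  coli1 <- paste0("COLI1_", optSel)
  coli2 <- paste0("COLI2_", optSel)
  sets <- list("F1" = alsSel, "F2" = optSel,
               "F1+2" = c(alsSel, optSel),
               "F4" = coli1, "F5" = coli2,
               "F2+3" = c(optSel, blv),
               "F1+2+4" = c(alsSel, optSel, coli1),
               "F1+2+5" = c(alsSel, optSel, coli2))
  if (!id %in% names(sets))
    stop("unknown experiment id '", id, "'; valid: ",
         paste(names(sets), collapse = ", "))
  cols <- unique(sets[[id]])
  .requireCols(table, c(cols, response))
  keep <- c(intersect("plot_id", names(table)), cols, response)
  table[, keep, drop = FALSE]
}
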
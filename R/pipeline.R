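# End-to-end drivers for synthetic scenes: cloud preprocessing + metric
# extraction, optical feature derivation, the two-step selection on each
# source, COLI fusion, and experiment-set assembly. These are the
# functions the evaluation harness and the acceptance script call.

#' ALS feature table for a scene
#'
#' Optionally denoises each plot cloud, builds a per-plot IDW DTM from
#' the labelled ground returns, normalizes heights and extracts the full
#' ALS metric table. On the generator's flat default terrain the clouds
#' can be used directly with `normalize = FALSE` (ground elevation is a
#' known constant), which skips the per-plot DTM at identical metric
#' values up to the DTM's interpolation error.
#'
#' @param scene result of [buildScene()].
#' @param normalize run the DTM + normalization chain (default `TRUE`).
#' @param denoise run [removeNoise()] first (default `FALSE`; generated
#'   clouds contain no gross outliers).
#' @param dtmCellSize DTM resolution (m), default 0.5.
#' @return data.frame `plot_id` + ALS metrics + `agb`.
#' @export
alsFeatureTable <- function(scene, normalize = TRUE, denoise = FALSE,
                            dtmCellSize = 0.5) {
  clouds <- scene$clouds
  if (denoise) clouds <- lapply(clouds, removeNoise)
  if (normalize) {
    clouds <- lapply(clouds, function(cl) {
      if (nPoints(cl) == 0) return(initialize(cl, normalized = TRUE))
      normalizeHeights(cl, interpolateDtmIdw(cl, cellSize = dtmCellSize))
    })
  } else {
    base <- 100  # generator terrain datum
    clouds <- lapply(clouds, function(cl) {
      p <- cloudPoints(cl)
      if (nrow(p)) p$z <- p$z - .terrainElev(scene$config, p$x, p$y, base)
      initialize(cl, points = p, normalized = TRUE)
    })
  }
  tab <- extractAlsMetrics(clouds)
  merge(tab, scene$truth[, c("plot_id", "agb_mg_ha")], by = "plot_id")
}

#' Optical feature table for a scene
#'
#' Applies the optical chain of [opticalFeatureTable()] to the scene
#' raster (constant slope/aspect from the scene configuration) and joins
#' the ground-truth response.
#'
#' @param scene result of [buildScene()].
#' @param mode plot sampling mode.
#' @return data.frame `plot_id` + optical features + `agb`.
#' @export
sceneOpticalTable <- function(scene, mode = "center") {
  tab <- opticalFeatureTable(scene$raster, scene$plots,
                             slopeDeg = scene$slopeDeg,
                             aspectDeg = scene$aspectDeg, mode = mode)
  merge(tab, scene$truth[, c("plot_id", "agb_mg_ha")], by = "plot_id")
}

.renameAgb <- function(tab) {
  names(tab)[names(tab) == "agb_mg_ha"] <- "agb"
  tab
}

#' Full feature preparation for the experiment grid
#'
#' Runs the two-step selection on the ALS and optical tables separately
#' (k features per source), determines the best LiDAR variable among the
#' selected ALS features, computes all COLI1/COLI2 fusion columns, and
#' returns the merged table with everything needed by
#' [assembleExperiment()].
#'
#' @param scene result of [buildScene()].
#' @param k selected features per source, default 9.
#' @param budget budget profile name or list (scales the selection
#'   forests).
#' @param seeds seeds of the repeated importance ranking, default 0..9.
#' @param normalize passed to [alsFeatureTable()].
#' @return list: `table` (merged features + `agb`), `alsSel`, `optSel`,
#'   `blv`, `blvReport`, `alsSelection`, `optSelection`.
#' @export
prepareExperimentFeatures <- function(scene, k = 9, budget = "full",
                                      seeds = 0:9, normalize = TRUE) {
  b <- if (is.character(budget)) budgetProfile(budget) else budget
  als <- .renameAgb(alsFeatureTable(scene, normalize = normalize))
  opt <- .renameAgb(sceneOpticalTable(scene))
  # drop non-finite feature columns (degenerate metrics) before selection
  clean <- function(tab) {
    keep <- vapply(tab, function(col) !is.numeric(col) ||
                     all(is.finite(col)), TRUE)
    tab[, keep, drop = FALSE]
  }
  als <- clean(als); opt <- clean(opt)
  selA <- selectFeatures(als, k = k, seeds = seeds, nTrees = b$selTrees)
  selO <- selectFeatures(opt, k = k, seeds = seeds, nTrees = b$selTrees)
  blv <- bestLidarVariable(als, features = selA$selected)
  merged <- merge(als[, c("plot_id", selA$selected, "agb")],
                  opt[, c("plot_id", selO$selected)], by = "plot_id")
  merged <- computeColi1(merged, selO$selected, blv$best)
  merged <- computeColi2(merged, selO$selected, blv$best)
  list(table = merged, alsSel = selA$selected, optSel = selO$selected,
       blv = blv$best, blvReport = blv$report, alsSelection = selA,
       optSelection = selO)
}

#' Experiment feature sets for a prepared scene
#'
#' @param prep result of [prepareExperimentFeatures()].
#' @param ids feature-set ids, default all eight.
#' @return named list of feature tables for [runExperiments()].
#' @export
experimentFeatureSets <- function(prep, ids = c("F1", "F2", "F1+2", "F4",
                                                "F5", "F2+3", "F1+2+4",
                                                "F1+2+5")) {
  sets <- lapply(ids, function(id)
    assembleExperiment(prep$table, id, prep$alsSel, prep$optSel,
                       prep$blv))
  names(sets) <- ids
  sets
}
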
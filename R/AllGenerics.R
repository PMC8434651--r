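#' Number of returns in a cloud
#' @param x a [LidarCloud-class]
#' @return integer count
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname nPoints
#' @export
setMethod("nPoints", "LidarCloud", function(x) nrow(x@points))

#' Access the per-return table of a cloud
#' @param x a [LidarCloud-class]
#' @return data.frame of returns
#' @export
setGeneric("cloudPoints", function(x) standardGeneric("cloudPoints"))

#' @rdname cloudPoints
#' @export
setMethod("cloudPoints", "LidarCloud", function(x) x@points)

#' Layer names of a raster stack
#' @param x a [BandStack-class]
#' @return character vector
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname layerNames
#' @export
setMethod("layerNames", "BandStack", function(x) x@layerNames)

#' Extract one layer of a stack as a matrix
#' @param x a [BandStack-class]
#' @param name layer name
#' @return numeric matrix
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))

#' @rdname getLayer
#' @export
setMethod("getLayer", "BandStack", function(x, name) {
  i <- match(name, x@layerNames)
  if (is.na(i)) stop("no layer named '", name, "'")
  x@values[, , i]
})

setMethod("show", "LidarCloud", function(object) {
  p <- object@points
  cat("LidarCloud:", nrow(p), "returns",
      if (object@normalized) "(height-normalized)" else "(raw elevation)",
      "\n")
  if (nrow(p)) {
    cat("  z range:", sprintf("%.2f..%.2f m", min(p$z), max(p$z)), "\n")
    cat("  classes:", paste(sprintf("%s=%d", names(table(p$classification)),
                                    table(p$classification)), collapse = " "),
        "\n")
  }
  invisible(object)
})

setMethod("show", "BandStack", function(object) {
  d <- dim(object@values)
  cat("BandStack:", d[1], "x", d[2], "cells,", d[3], "layers,",
      object@cellSize, "m cells\n")
  cat("  layers:", paste(utils::head(object@layerNames, 8), collapse = ", "),
      if (d[3] > 8) "..." else "", "\n")
  invisible(object)
})

setMethod("show", "AgbModel", function(object) {
  cat("AgbModel:", object@algorithm, "on", length(object@featureNames),
      "features (seed", object@spec$seed, ")\n")
  invisible(object)
})

setMethod("show", "AgbStackModel", function(object) {
  cat("AgbStackModel: bases",
      paste(vapply(object@baseModels, function(m) m@algorithm, ""),
            collapse = "+"),
      "-> meta", object@metaModel@algorithm, "\n")
  invisible(object)
})

setMethod("show", "SceneConfig", function(object) {
  cat("SceneConfig:", object@nPlots, "plots of", object@plotWidth, "x",
      object@plotHeight, "m,", object@pointDensity, "pts/m^2, seed",
      object@seed, "\n")
  invisible(object)
})

setMethod("show", "PredictionMap", function(object) {
  cat("PredictionMap:", nrow(object@agb), "x", ncol(object@agb),
      "pixels;", sum(!is.na(object@agb)), "predicted\n")
  s <- object@summary
  cat(sprintf("  AGB Mg/ha: min %.2f, max %.2f, mean %.2f, sd %.2f\n",
              s["min"], s["max"], s["mean"], s["sd"]))
  invisible(object)
})
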
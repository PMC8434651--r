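#' @import methods
NULL

#' Discrete-return LiDAR point cloud
#'
#' Container for the returns of one plot (or tile): planimetric position,
#' elevation (or normalized height), intensity, return number and a
#' ground / non-ground / noise classification.
#'
#' @slot points data.frame with columns `x`, `y`, `z` (metres), `intensity`
#'   (arbitrary units, >= 0), `return_number` (integer >= 1) and
#'   `classification` (one of `"ground"`, `"nonground"`, `"noise"`).
#' @slot normalized logical; `TRUE` once `z` holds height above ground.
#' @export
setClass("LidarCloud",
  representation(points = "data.frame", normalized = "logical"),
  prototype(points = data.frame(x = numeric(), y = numeric(), z = numeric(),
                                intensity = numeric(),
                                return_number = integer(),
                                classification = character(),
                                stringsAsFactors = FALSE),
            normalized = FALSE),
  validity = function(object) {
    p <- object@points
    need <- c("x", "y", "z", "intensity", "return_number", "classification")
    if (!all(need %in% names(p)))
      return(paste("points must have columns:", paste(need, collapse = ", ")))
    if (nrow(p)) {
      if (!all(is.finite(p$x)) || !all(is.finite(p$y)) || !all(is.finite(p$z)))
        return("coordinates must be finite")
      if (any(p$intensity < 0)) return("intensity must be >= 0")
      if (!all(p$classification %in% c("ground", "nonground", "noise")))
        return("classification must be ground/nonground/noise")
    }
    TRUE
  })

#' Regular digital terrain model grid
#'
#' @slot elevation numeric matrix of ground elevation (m); row 1 is the
#'   northernmost (largest y) row.
#' @slot origin numeric length 2, `c(xmin, ymin)` of the grid extent.
#' @slot cellSize cell edge length in metres.
#' @export
setClass("DtmGrid",
  representation(elevation = "matrix", origin = "numeric",
                 cellSize = "numeric"),
  validity = function(object) {
    if (length(object@origin) != 2) return("origin must be length 2")
    if (object@cellSize <= 0) return("cellSize must be > 0")
    TRUE
  })

#' Multiband raster stack
#'
#' Georeferenced (projected metres, arbitrary CRS) stack of aligned grids:
#' surface-reflectance bands and any derived feature layers. Row 1 is the
#' northernmost row; values may be NA where masked.
#'
#' @slot values 3-d numeric array `nrow x ncol x nlayers`.
#' @slot layerNames character vector naming the third dimension.
#' @slot origin numeric `c(xmin, ymin)` of the extent.
#' @slot cellSize cell edge length in metres (30 for the reflectance grids).
#' @export
setClass("BandStack",
  representation(values = "array", layerNames = "character",
                 origin = "numeric", cellSize = "numeric"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3) return("values must be a 3-d array")
    if (d[3] != length(object@layerNames))
      return("layerNames must match the third dimension")
    if (anyDuplicated(object@layerNames)) return("duplicate layer names")
    if (object@cellSize <= 0) return("cellSize must be > 0")
    TRUE
  })

#' Synthetic forest scene configuration
#'
#' Generative parameters for [buildScene()]: plot geometry, stand structure,
#' the canopy height-biomass link, the saturating reflectance response and
#' the noise levels of every channel. Defaults emulate a temperate natural
#' secondary forest inventoried with 20 m x 30 m plots and ALS at
#' 3.6 points per square metre; see the methods vignette for why each
#' default was chosen (species composition and stand density are plausible
#' placeholders, not measured values).
#'
#' @slot nPlots number of plots.
#' @slot plotWidth,plotHeight plot dimensions (m); default 20 x 30.
#' @slot pointDensity ALS return density (points per m^2); default 3.6.
#' @slot stemsLambda Poisson mean of the stem count per plot (trees with
#'   DBH >= 5 cm); default 60.
#' @slot speciesMix named numeric vector of species mixing proportions
#'   (names must be species of [allometryTable()]); sums to 1.
#' @slot dbhWeibull named list mapping species to `c(shape, scale)` of the
#'   DBH Weibull (cm), truncated below at 5 cm. Species absent from the
#'   list use the `"default"` entry.
#' @slot h0,gamma canopy top-height link H = h0 * AGB^gamma (H in m, AGB in
#'   Mg/ha).
#' @slot groundFraction expected fraction of returns that are ground hits.
#' @slot bandParams 7 x 3 matrix (`r0`, `r1`, `s`): band reflectance
#'   r0 + r1 * exp(-AGB / s) before noise; `s` in Mg/ha.
#' @slot bandNoiseSd per-band Gaussian reflectance noise SD.
#' @slot zNoiseSd ranging noise SD on return elevation (m).
#' @slot intensityI0,intensityK,intensityNoiseSd intensity model
#'   I = I0 * exp(-k * (H - z)) + noise.
#' @slot slopeDeg,aspectDeg planar terrain slope and aspect (degrees); the
#'   only topography simulated, used to exercise SCS+C correction.
#' @slot seed master integer seed; all randomness flows from it through
#'   per-plot substreams.
#' @export
setClass("SceneConfig",
  representation(nPlots = "integer", plotWidth = "numeric",
                 plotHeight = "numeric", pointDensity = "numeric",
                 stemsLambda = "numeric", speciesMix = "numeric",
                 dbhWeibull = "list", h0 = "numeric", gamma = "numeric",
                 groundFraction = "numeric", bandParams = "matrix",
                 bandNoiseSd = "numeric", zNoiseSd = "numeric",
                 intensityI0 = "numeric", intensityK = "numeric",
                 intensityNoiseSd = "numeric", slopeDeg = "numeric",
                 aspectDeg = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@nPlots < 0) return("nPlots must be >= 0")
    if (object@plotWidth <= 0 || object@plotHeight <= 0)
      return("plot dimensions must be > 0")
    if (object@pointDensity <= 0) return("pointDensity must be > 0")
    if (abs(sum(object@speciesMix) - 1) > 1e-9)
      return("speciesMix proportions must sum to 1")
    if (any(object@speciesMix < 0)) return("speciesMix must be >= 0")
    if (!all(dim(object@bandParams) == c(7, 3)))
      return("bandParams must be 7 x 3 (r0, r1, s)")
    if (any(object@bandParams[, 3] <= 0))
      return("saturation constants s must be > 0")
    if (object@groundFraction < 0 || object@groundFraction > 1)
      return("groundFraction must be in [0, 1]")
    TRUE
  })

#' Fitted base AGB regression model
#'
#' Uniform wrapper for the eight base algorithms: the opaque fitted state,
#' the training feature names and any internal standardization parameters.
#' Prediction refuses feature tables whose columns do not match training.
#'
#' @slot algorithm one of MLR, ELM, BP, RegT, RF, SVR, KNN, CNN.
#' @slot spec resolved hyperparameter list (including seed).
#' @slot fit opaque fitted object.
#' @slot featureNames training feature columns, in training order.
#' @slot xCenter,xScale,yCenter,yScale standardization parameters (identity
#'   for the tree models and MLR).
#' @export
setClass("AgbModel",
  representation(algorithm = "character", spec = "list", fit = "ANY",
                 featureNames = "character", xCenter = "numeric",
                 xScale = "numeric", yCenter = "numeric", yScale = "numeric"))

#' Two-layer stacked generalization ensemble
#'
#' @slot baseModels list of [AgbModel-class] refit on the full training set.
#' @slot metaModel [AgbModel-class] fit on out-of-fold base predictions.
#' @slot spec the resolved stack specification.
#' @export
setClass("AgbStackModel",
  representation(baseModels = "list", metaModel = "AgbModel", spec = "list"))

#' Wall-to-wall AGB prediction map
#'
#' @slot agb numeric matrix of predicted AGB (Mg/ha), NA where any input
#'   layer was missing.
#' @slot origin,cellSize grid georeferencing as in [BandStack-class].
#' @slot summary named numeric: min, max, mean, sd over non-NA pixels.
#' @export
setClass("PredictionMap",
  representation(agb = "matrix", origin = "numeric", cellSize = "numeric",
                 summary = "numeric"))
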
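# Two-layer stacked generalization. The meta model consumes only the
# base models' predictions. Meta training uses leakage-safe out-of-fold
# base predictions (seeded K-fold, default K = 5); the in-sample variant
# is available behind `inner = "naive"` for comparison but is known to
# leak the training response into the meta features.

#' Stack specification
#'
#' @param baseSpecs ordered list of [modelSpec()] objects (>= 2); default
#'   RF, SVR, KNN, CNN.
#' @param metaSpec a [modelSpec()] for the meta model (one of the same
#'   algorithm set).
#' @param innerK inner folds for out-of-fold meta features, default 5.
#' @param seed master seed (fold assignment and per-fit seed derivation).
#' @param inner `"oof"` (default, out-of-fold) or `"naive"` (in-sample).
#' @return list of class `"agb_stack_spec"`.
#' @export
stackSpec <- function(baseSpecs = list(modelSpec("RF"), modelSpec("SVR"),
                                       modelSpec("KNN"), modelSpec("CNN")),
                      metaSpec = modelSpec("RF"), innerK = 5L, seed = 10L,
                      inner = c("oof", "naive")) {
  if (length(baseSpecs) < 2) stop("need at least 2 base models")
  structure(list(baseSpecs = baseSpecs, metaSpec = metaSpec,
                 innerK = as.integer(innerK), seed = as.integer(seed),
                 inner = match.arg(inner)),
            class = "agb_stack_spec")
}

.baseColnames <- function(spec)
  sprintf("base%d_%s", seq_along(spec$baseSpecs),
          vapply(spec$baseSpecs, `[[`, "", "algorithm"))

.withSeed <- function(spec, seed) { spec$seed <- as.integer(seed); spec }

#' Out-of-fold meta training features
#'
#' Seeded K-fold partition; for every fold, each base model is trained on
#' the complement and predicts the fold, so row i's meta features never
#' depend on y_i.
#'
#' @param spec a [stackSpec()].
#' @param X feature table (data.frame/matrix).
#' @param y response vector.
#' @param budget a budget profile name or list (see [budgetProfile()]).
#' @return list: `Z` (n x n_base matrix of out-of-fold predictions,
#'   columns in base order), `folds` (assignment), `y`.
#' @export
buildMetaFeatures <- function(spec, X, y, budget = "full") {
  n <- nrow(X)
  K <- spec$innerK
  if (K > n) stop("innerK (", K, ") exceeds n (", n, ")")
  if (K < 2) stop("innerK must be >= 2")
  set.seed(spec$seed)
  folds <- sample(rep(seq_len(K), length.out = n))
  nb <- length(spec$baseSpecs)
  Z <- matrix(NA_real_, n, nb, dimnames = list(NULL, .baseColnames(spec)))
  if (spec$inner == "naive") {
    for (b in seq_len(nb)) {
      bs <- .applyBudget(.withSeed(spec$baseSpecs[[b]],
                                   spec$seed + 131 * b), budget)
      Z[, b] <- predict(fitModel(bs, X, y), X)
    }
    return(list(Z = Z, folds = folds, y = y))
  }
  for (f in seq_len(K)) {
    te <- folds == f
    for (b in seq_len(nb)) {
      bs <- .applyBudget(.withSeed(spec$baseSpecs[[b]],
                                   spec$seed + 131 * b + 17 * f), budget)
      m <- fitModel(bs, X[!te, , drop = FALSE], y[!te])
      Z[te, b] <- predict(m, X[te, , drop = FALSE])
    }
  }
  list(Z = Z, folds = folds, y = y)
}

#' Fit a stacked generalization ensemble
#'
#' The meta model is fit on the (out-of-fold) base-prediction matrix; the
#' base models are then refit on the full training set for deployment.
#'
#' @inheritParams buildMetaFeatures
#' @return an [AgbStackModel-class].
#' @export
fitStack <- function(spec, X, y, budget = "full") {
  stopifnot(inherits(spec, "agb_stack_spec"))
  X <- as.data.frame(X)
  mf <- buildMetaFeatures(spec, X, y, budget)
  meta <- fitModel(.applyBudget(.withSeed(spec$metaSpec, spec$seed + 997),
                                budget),
                   as.data.frame(mf$Z), y)
  bases <- lapply(seq_along(spec$baseSpecs), function(b)
    fitModel(.applyBudget(.withSeed(spec$baseSpecs[[b]],
                                    spec$seed + 131 * b), budget), X, y))
  new("AgbStackModel", baseModels = bases, metaModel = meta,
      spec = unclass(spec))
}

#' Predict AGB from a stacked ensemble
#'
#' Base predictions on the new data are assembled in spec order and fed
#' to the meta model.
#'
#' @param object an [AgbStackModel-class].
#' @param newdata feature table with the training columns.
#' @return numeric prediction vector.
#' @export
setMethod("predict", "AgbStackModel", function(object, newdata) {
  Z <- vapply(object@baseModels, function(m) predict(m, newdata),
              numeric(nrow(as.data.frame(newdata))))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  colnames(Z) <- object@metaModel@featureNames
  predict(object@metaModel, as.data.frame(Z))
})
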
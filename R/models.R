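# The eight base regression algorithms behind one uniform fit/predict
# contract. Stated hyperparameter defaults: BP 1000 epochs; RF 1000
# trees, random state 10; SVR linear kernel, cost 1; KNN k = 5, uniform
# weights; CNN 1000 epochs, batch 30, one hidden (conv) layer. Where the
# remaining knobs are open they are pinned as documented defaults: ELM
# 64 sigmoid hidden units; BP one 32-unit sigmoid hidden layer; SVR
# epsilon 0.1; RegT unconstrained depth, minimum leaf 1; CNN kernel 3,
# 32 filters, Adam at 1e-3.
#
# Features are standardized internally (training mean/SD) for ELM, BP,
# SVR, KNN and CNN, and the targets of ELM/BP/SVR/CNN are standardized
# too (predictions un-standardized); MLR and the tree models see the raw
# scales.

.ALGORITHMS <- c("MLR", "ELM", "BP", "RegT", "RF", "SVR", "KNN", "CNN")
.SCALE_X <- c("ELM", "BP", "SVR", "KNN", "CNN")
.SCALE_Y <- c("ELM", "BP", "SVR", "CNN")

#' Base model specification
#'
#' @param algorithm one of `"MLR"`, `"ELM"`, `"BP"`, `"RegT"`, `"RF"`,
#'   `"SVR"`, `"KNN"`, `"CNN"`.
#' @param seed integer seed for every stochastic element.
#' @param ... hyperparameter overrides: `hiddenUnits` (ELM, 64), `bpSize`
#'   / `bpMaxit` (BP, 32 / 1000), `nTrees` (RF, 1000), `cost` / `epsilon`
#'   (SVR, 1 / 0.1), `k` (KNN, 5), `cnnEpochs` / `cnnBatch` /
#'   `cnnFilters` / `cnnKernel` / `cnnLr` (CNN, 1000 / 30 / 32 / 3 /
#'   1e-3).
#' @return a list of class `"agb_model_spec"`.
#' @examples
#' modelSpec("RF", seed = 10)
#' @export
modelSpec <- function(algorithm, seed = 10L, ...) {
  algorithm <- match.arg(algorithm, .ALGORITHMS)
  spec <- list(algorithm = algorithm, seed = as.integer(seed),
               hiddenUnits = 64L, bpSize = 32L, bpMaxit = 1000L,
               nTrees = 1000L, cost = 1, epsilon = 0.1, k = 5L,
               cnnEpochs = 1000L, cnnBatch = 30L, cnnFilters = 32L,
               cnnKernel = 3L, cnnLr = 1e-3)
  over <- list(...)
  bad <- setdiff(names(over), names(spec))
  if (length(bad)) stop("unknown hyperparameter(s): ",
                        paste(bad, collapse = ", "))
  spec[names(over)] <- over
  class(spec) <- "agb_model_spec"
  spec
}

#' Resolve a computation-budget profile
#'
#' Scales the expensive training knobs for desk-scale runs; the model
#' classes, seeding and data flow are untouched, so results are
#' comparable in structure but cheaper. `"full"` mirrors the stated
#' hyperparameters; `"small"` uses CNN epochs 100, RF trees 200, inner
#' stacking folds 3, BP maxit 200 and 200 selection trees; `"tiny"` (for
#' quick determinism-style checks) shrinks further.
#'
#' @param budget `"full"`, `"small"` or `"tiny"`.
#' @return named list `cnnEpochs`, `nTrees`, `innerK`, `bpMaxit`,
#'   `selTrees`.
#' @export
budgetProfile <- function(budget = c("full", "small", "tiny")) {
  budget <- match.arg(budget)
  switch(budget,
    full = list(cnnEpochs = 1000L, nTrees = 1000L, innerK = 5L,
                bpMaxit = 1000L, selTrees = 1000L),
    small = list(cnnEpochs = 100L, nTrees = 200L, innerK = 3L,
                 bpMaxit = 200L, selTrees = 200L),
    tiny = list(cnnEpochs = 30L, nTrees = 50L, innerK = 3L,
                bpMaxit = 50L, selTrees = 50L))
}

.applyBudget <- function(spec, budget) {
  b <- if (is.character(budget)) budgetProfile(budget) else budget
  spec$cnnEpochs <- min(spec$cnnEpochs, b$cnnEpochs)
  spec$nTrees <- min(spec$nTrees, b$nTrees)
  spec$bpMaxit <- min(spec$bpMaxit, b$bpMaxit)
  spec
}

.standardize <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' Train an extreme learning machine readout
#'
#' Hidden weights and biases are drawn once from a seeded uniform(-1, 1)
#' and frozen; the readout (with an output intercept) is the minimum-norm
#' least-squares solution on the hidden activations (Moore-Penrose
#' pseudo-inverse), so a rank-deficient activation matrix is handled, not
#' an error.
#'
#' @param X standardized feature matrix.
#' @param y response vector.
#' @param hiddenUnits hidden layer width, default 64.
#' @param activation `"sigmoid"` (default), `"tanh"` or `"linear"`.
#' @param seed seed for the hidden weights.
#' @return list `W`, `b`, `beta`, `activation`.
#' @export
elmTrain <- function(X, y, hiddenUnits = 64, activation = "sigmoid",
                     seed = 10L) {
  if (hiddenUnits < 1) stop("hiddenUnits must be >= 1")
  set.seed(seed)
  W <- matrix(stats::runif(ncol(X) * hiddenUnits, -1, 1), ncol(X),
              hiddenUnits)
  b <- stats::runif(hiddenUnits, -1, 1)
  H <- cbind(.elmAct(X %*% W + rep(b, each = nrow(X)), activation), 1)
  beta <- MASS::ginv(H) %*% y
  list(W = W, b = b, beta = beta, activation = activation)
}

.elmAct <- function(A, activation) {
  switch(activation,
         sigmoid = 1 / (1 + exp(-A)),
         tanh = tanh(A),
         linear = A,
         stop("unknown activation"))
}

#' Predict from a trained ELM readout
#'
#' @param fit result of [elmTrain()].
#' @param X feature matrix on the training (standardized) scale.
#' @return numeric prediction vector.
#' @export
elmPredict <- function(fit, X)
  as.vector(cbind(.elmAct(X %*% fit$W + rep(fit$b, each = nrow(X)),
                          fit$activation), 1) %*% fit$beta)

.elmPredict <- elmPredict

#' Fit a base AGB regression model
#'
#' Uniform entry point for the eight algorithms. Input checks: no
#' missing values; KNN needs at least k training rows. All stochastic
#' algorithms are fully seeded through the spec.
#'
#' @param spec a [modelSpec()].
#' @param X data.frame or matrix of numeric features.
#' @param y numeric response (AGB, Mg/ha).
#' @return an [AgbModel-class].
#' @examples
#' X <- data.frame(a = 1:10)
#' fitModel(modelSpec("MLR"), X, 2 * X$a + 1)
#' @export
fitModel <- function(spec, X, y) {
  stopifnot(inherits(spec, "agb_model_spec"))
  X <- as.data.frame(X)
  feats <- names(X)
  Xm <- as.matrix(X)
  if (!is.numeric(Xm) || anyNA(Xm) || any(!is.finite(Xm)))
    stop("X must be numeric with no missing values")
  if (anyNA(y)) stop("y contains missing values")
  if (length(y) != nrow(Xm)) stop("X and y lengths differ")
  alg <- spec$algorithm
  if (alg == "KNN" && nrow(Xm) < spec$k)
    stop("KNN needs at least k = ", spec$k, " training rows")

  xc <- rep(0, ncol(Xm)); xs <- rep(1, ncol(Xm))
  if (alg %in% .SCALE_X) {
    st <- .standardize(Xm)
    Xm <- st$X; xc <- st$center; xs <- st$scale
  }
  yc <- 0; ys <- 1
  yt <- y
  if (alg %in% .SCALE_Y) {
    yc <- mean(y); ys <- stats::sd(y)
    if (ys == 0 || !is.finite(ys)) ys <- 1
    yt <- (y - yc) / ys
  }

  fit <- switch(alg,
    MLR = {
      df <- as.data.frame(Xm); df$.y <- yt
      stats::lm(.y ~ ., data = df)
    },
    ELM = elmTrain(Xm, yt, spec$hiddenUnits, seed = spec$seed),
    BP = {
      set.seed(spec$seed)
      nnet::nnet(Xm, yt, size = spec$bpSize, linout = TRUE, decay = 0,
                 maxit = spec$bpMaxit, trace = FALSE, MaxNWts = 1e5)
    },
    RegT = {
      df <- as.data.frame(Xm); df$.y <- yt
      set.seed(spec$seed)
      rpart::rpart(.y ~ ., data = df,
                   control = rpart::rpart.control(minsplit = 2,
                                                  minbucket = 1, cp = 0,
                                                  xval = 0))
    },
    RF = {
      set.seed(spec$seed)
      randomForest::randomForest(x = as.data.frame(Xm), y = yt,
                                 ntree = spec$nTrees)
    },
    SVR = {
      set.seed(spec$seed)
      e1071::svm(x = Xm, y = yt, kernel = "linear", cost = spec$cost,
                 epsilon = spec$epsilon, scale = FALSE)
    },
    KNN = caret::knnreg(Xm, yt, k = spec$k),
    CNN = .cnnTrain(Xm, yt, filters = spec$cnnFilters,
                    kernel = spec$cnnKernel, epochs = spec$cnnEpochs,
                    batchSize = spec$cnnBatch, lr = spec$cnnLr,
                    seed = spec$seed))

  new("AgbModel", algorithm = alg, spec = unclass(spec), fit = fit,
      featureNames = feats, xCenter = xc, xScale = xs, yCenter = yc,
      yScale = ys)
}

#' Predict AGB from a fitted base model
#'
#' Columns must match the training features exactly (order-insensitive);
#' missing or extra columns are an error listing the names.
#'
#' @param object an [AgbModel-class].
#' @param newdata data.frame or matrix of features.
#' @return numeric vector of predictions on the response scale.
#' @export
setMethod("predict", "AgbModel", function(object, newdata) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object@featureNames, names(newdata))
  extra <- setdiff(names(newdata), object@featureNames)
  if (length(miss) || length(extra))
    stop("feature mismatch;",
         if (length(miss)) paste0(" missing: ",
                                  paste(miss, collapse = ", ")) else "",
         if (length(extra)) paste0(" extra: ",
                                   paste(extra, collapse = ", ")) else "")
  Xm <- as.matrix(newdata[, object@featureNames, drop = FALSE])
  Xm <- sweep(sweep(Xm, 2, object@xCenter), 2, object@xScale, "/")
  p <- switch(object@algorithm,
    MLR = stats::predict(object@fit, as.data.frame(Xm)),
    ELM = .elmPredict(object@fit, Xm),
    BP = as.vector(stats::predict(object@fit, Xm)),
    RegT = stats::predict(object@fit, as.data.frame(Xm)),
    RF = stats::predict(object@fit, as.data.frame(Xm)),
    SVR = as.vector(stats::predict(object@fit, Xm)),
    KNN = stats::predict(object@fit, Xm),
    CNN = .cnnPredict(object@fit, Xm))
  as.vector(p) * object@yScale + object@yCenter
})
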
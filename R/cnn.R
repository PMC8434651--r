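# A small 1-d convolutional network for tabular regression, written
# directly against base linear algebra and trained with Adam: conv
# (kernel min(3, p), 32 filters) over the standardized feature vector,
# ReLU, global average pooling, dense scalar head, MSE loss. Everything
# is seeded: initialization and the per-epoch shuffles derive from one
# seed, so training is exactly reproducible.
#
# The convolution over all window positions is evaluated as one matrix
# product on a row-stacked patch matrix (rows grouped by position), so a
# training step costs two large GEMMs instead of a loop of small ones.

.cnnInit <- function(p, filters, kernel, seed) {
  set.seed(seed)
  k <- min(kernel, p)
  list(k = k, npos = p - k + 1L, filters = filters,
       Wc = matrix(stats::rnorm(k * filters, 0, sqrt(2 / k)), k, filters),
       bc = rep(0, filters),
       Wd = matrix(stats::rnorm(filters, 0, sqrt(2 / filters)), filters, 1),
       bd = 0)
}

# (n * npos) x k matrix whose row block j holds X[, j:(j + k - 1)]
.cnnPatches <- function(X, k, npos) {
  n <- nrow(X)
  colIdx <- as.vector(outer(seq_len(k), seq_len(npos) - 1L, `+`))
  arr <- array(X[, colIdx, drop = FALSE], c(n, k, npos))
  matrix(aperm(arr, c(1, 3, 2)), n * npos, k)
}

.cnnForwardStacked <- function(par, P, n) {
  A <- P %*% par$Wc
  A <- A + rep(par$bc, each = nrow(A))
  H <- A * (A > 0)
  G <- matrix(0, n, par$filters)
  for (j in seq_len(par$npos))
    G <- G + H[((j - 1L) * n + 1L):(j * n), , drop = FALSE]
  G <- G / par$npos
  list(A = A, G = G, yhat = as.vector(G %*% par$Wd + par$bd))
}

.cnnPredict <- function(par, X)
  .cnnForwardStacked(par, .cnnPatches(X, par$k, par$npos), nrow(X))$yhat

.cnnTrain <- function(X, y, filters = 32, kernel = 3, epochs = 1000,
                      batchSize = 30, lr = 1e-3, seed = 1) {
  par <- .cnnInit(ncol(X), filters, kernel, seed)
  n <- nrow(X)
  P <- .cnnPatches(X, par$k, par$npos)  # fixed across epochs
  npos <- par$npos
  filters <- par$filters
  Wc <- par$Wc; bc <- par$bc; Wd <- par$Wd; bd <- par$bd
  mWc <- Wc * 0; vWc <- Wc * 0; mbc <- bc * 0; vbc <- bc * 0
  mWd <- Wd * 0; vWd <- Wd * 0; mbd <- 0; vbd <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  set.seed(seed + 1L)
  starts <- seq(1, n, by = batchSize)
  posOff <- n * (seq_len(npos) - 1L)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    for (start in starts) {
      bi <- idx[start:min(start + batchSize - 1, n)]
      nb <- length(bi)
      rows <- rep(bi, npos) + rep(posOff, each = nb)
      Pb <- P[rows, , drop = FALSE]
      A <- Pb %*% Wc
      A <- A + rep(bc, each = nb * npos)
      pos <- A > 0
      H <- A * pos
      G <- H[seq_len(nb), , drop = FALSE]
      for (j in seq_len(npos - 1L))
        G <- G + H[(j * nb + 1L):((j + 1L) * nb), , drop = FALSE]
      G <- G / npos
      yhat <- as.vector(G %*% Wd) + bd
      dy <- 2 * (yhat - y[bi]) / nb          # d MSE / d yhat
      gWd <- crossprod(G, dy)
      gbd <- sum(dy)
      dG <- (dy %*% t(Wd)) / npos            # nb x filters
      dA <- dG[rep(seq_len(nb), npos), , drop = FALSE] * pos
      gWc <- crossprod(Pb, dA)
      gbc <- colSums(dA)
      step <- step + 1
      c1 <- 1 / (1 - b1^step); c2 <- 1 / (1 - b2^step)
      mWc <- b1 * mWc + (1 - b1) * gWc
      vWc <- b2 * vWc + (1 - b2) * gWc^2
      Wc <- Wc - lr * (mWc * c1) / (sqrt(vWc * c2) + eps)
      mbc <- b1 * mbc + (1 - b1) * gbc
      vbc <- b2 * vbc + (1 - b2) * gbc^2
      bc <- bc - lr * (mbc * c1) / (sqrt(vbc * c2) + eps)
      mWd <- b1 * mWd + (1 - b1) * gWd
      vWd <- b2 * vWd + (1 - b2) * gWd^2
      Wd <- Wd - lr * (mWd * c1) / (sqrt(vWd * c2) + eps)
      mbd <- b1 * mbd + (1 - b1) * gbd
      vbd <- b2 * vbd + (1 - b2) * gbd^2
      bd <- bd - lr * (mbd * c1) / (sqrt(vbd * c2) + eps)
    }
  }
  par$Wc <- Wc; par$bc <- bc; par$Wd <- Wd; par$bd <- bd
  par
}
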
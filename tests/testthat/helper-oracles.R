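# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (sort-and-index, pair enumeration, literal formula
# transcription) and share no code with the package implementation.

# linear-interpolation percentile between closest ranks (the pinned
# convention), computed from first principles
oraclePercentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p / 100
  lo <- floor(h)
  if (lo >= n - 1) return(s[n])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

# height-ordered cumulative intensity proportion of the lowest
# ceiling(k% * n) returns
oracleAii <- function(z, intensity, k) {
  ord <- order(z)
  m <- ceiling(k / 100 * length(z))
  sum(intensity[ord][seq_len(m)]) / sum(intensity)
}

oracleDensity <- function(z, nIntervals = 10, threshold = 2) {
  z <- z[z >= threshold]
  span <- max(z) - threshold
  if (span <= 0) return(c(1, rep(0, nIntervals - 1)))
  counts <- integer(nIntervals)
  for (zz in z) {
    i <- min(floor((zz - threshold) / span * nIntervals) + 1, nIntervals)
    counts[i] <- counts[i] + 1
  }
  counts / length(z)
}

# literal transcription of the six evaluation formulas
oracleMetrics <- function(y, yh) {
  n <- length(y)
  ybar <- sum(y) / n
  list(r2 = (sum((y - ybar) * (yh - sum(yh) / n)) /
               sqrt(sum((y - ybar)^2) * sum((yh - sum(yh) / n)^2)))^2,
       eq5_r2 = sum((yh - ybar)^2) / sum((y - ybar)^2),
       rmse = sqrt(sum((y - yh)^2) / n),
       rrmse = sqrt(sum((y - yh)^2) / n) / ybar,
       mae = sum(abs(y - yh)) / n,
       mape = 100 * sum(abs(y - yh) / y) / n,
       pm = sum((y - yh)^2) / sum((y - ybar)^2))
}

# GLCM statistics of one window by exhaustive enumeration of pixel pairs
# for the requested offsets (symmetric counting)
oracleGlcmWindow <- function(w, levels, offsets) {
  rng <- attr(w, "rng")
  q <- if (diff(rng) == 0) matrix(1L, nrow(w), ncol(w)) else {
    qq <- floor((w - rng[1]) / diff(rng) * levels) + 1L
    qq[qq > levels] <- levels
    qq
  }
  ii <- integer(0); jj <- integer(0)
  for (o in offsets) {
    for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
      r2 <- r + o[1]; c2 <- cc + o[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        ii <- c(ii, q[r, cc], q[r2, c2])
        jj <- c(jj, q[r2, c2], q[r, cc])
      }
    }
  }
  key <- paste(ii, jj)
  p <- as.vector(table(key)) / length(ii)
  lev <- do.call(rbind, strsplit(names(table(key)), " "))
  i <- as.numeric(lev[, 1]); j <- as.numeric(lev[, 2])
  mu <- sum(p * i)
  va <- sum(p * (i - mu)^2)
  list(entropy = -sum(p * log(p)),
       contrast = sum(p * (i - j)^2),
       homogeneity = sum(p / (1 + (i - j)^2)),
       asm = sum(p^2),
       mean = mu, var = va)
}

# a random synthetic cloud for metric-oracle checks
randomCloud <- function(n, seed) {
  set.seed(seed)
  new("LidarCloud",
      points = data.frame(
        x = runif(n, 0, 20), y = runif(n, 0, 30),
        z = c(runif(ceiling(n / 2), 0, 30), runif(floor(n / 2), 0, 1.5)),
        intensity = runif(n, 0, 500),
        return_number = sample.int(3, n, replace = TRUE),
        classification = "nonground", stringsAsFactors = FALSE),
      normalized = TRUE)
}

# small deterministic feature table with a linear response
linearTable <- function(n = 30, seed = 1, noise = 0) {
  set.seed(seed)
  X <- data.frame(a = runif(n, 0, 10), b = runif(n, 0, 10))
  data.frame(plot_id = sprintf("p%03d", seq_len(n)), X,
             agb = 10 * X$a + 2 * X$b + rnorm(n, 0, noise),
             stringsAsFactors = FALSE)
}

smallStack <- function(nr = 8, nc = 8, seed = 1, constant = NULL) {
  set.seed(seed)
  vals <- array(if (is.null(constant)) runif(nr * nc * 7, 0.01, 0.6)
                else constant, dim = c(nr, nc, 7))
  new("BandStack", values = vals, layerNames = paste0("B", 1:7),
      origin = c(0, 0), cellSize = 30)
}
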
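# Optical feature derivation: SCS+C topographic correction of the band
# stack, band combinations and vegetation indices, per-pixel GLCM
# (Haralick) textures, principal components, and plot sampling.
#
# Conventions pinned here because the upstream processing chain leaves
# them open: ND563 is read as a normalized difference (the printed dot
# treated as a typeset "/"; the literal product is available behind
# `nd563Product`); GLCM uses a 3x3 window, 32 grey levels, the four
# distance-1 offsets averaged, natural-log entropy; vegetation-index
# constants are the canonical literature values (EVI G=2.5, C1=6,
# C2=7.5, L=1; SAVI L=0.5).

#' SCS+C topographic correction
#'
#' Corrects each band as Lt = L * (cos(theta) * cos(alpha) + C) /
#' (cos(i) + C), with cos(i) = cos(theta) cos(alpha) +
#' sin(theta) sin(alpha) cos(phi_sun - aspect). When `C` is not supplied
#' it is estimated per band as intercept/slope of the regression
#' L = m * cos(i) + b over unmasked pixels. On flat terrain the factor is
#' exactly 1. Pixels where |cos(i) + C| falls below `tol` are masked with
#' a warning.
#'
#' @param stack a [BandStack-class] of reflectance bands.
#' @param slopeDeg,aspectDeg per-pixel matrices or scalars (degrees).
#' @param sunZenithDeg solar zenith angle (degrees; 90 - elevation).
#' @param sunAzimuthDeg solar azimuth (degrees).
#' @param C optional per-band semi-empirical constants (recycled).
#' @param tol denominator mask tolerance.
#' @return list with `stack` (corrected [BandStack-class]), `C` (named
#'   per-band constants) and `cosI` (incidence-cosine matrix).
#' @export
scsCCorrection <- function(stack, slopeDeg, aspectDeg, sunZenithDeg,
                           sunAzimuthDeg = 180, C = NULL, tol = 1e-6) {
  d <- dim(stack@values)
  asMat <- function(v) if (is.matrix(v)) v else matrix(v, d[1], d[2])
  alpha <- asMat(slopeDeg) * pi / 180
  aspect <- asMat(aspectDeg) * pi / 180
  theta <- sunZenithDeg * pi / 180
  phi <- sunAzimuthDeg * pi / 180
  cosI <- cos(theta) * cos(alpha) + sin(theta) * sin(alpha) *
    cos(phi - aspect)
  vals <- stack@values
  nb <- d[3]
  Cout <- numeric(nb)
  nMasked <- 0L
  for (b in seq_len(nb)) {
    L <- vals[, , b]
    ok <- is.finite(L) & is.finite(cosI)
    if (is.null(C)) {
      if (stats::sd(cosI[ok]) < 1e-12) {
        # no illumination variation (flat scene): factor is 1 for any C
        Cout[b] <- 0
      } else {
        fit <- stats::lm.fit(cbind(1, as.vector(cosI[ok])),
                             as.vector(L[ok]))
        m <- fit$coefficients[2]
        if (!is.finite(m) || abs(m) < 1e-12)
          stop("cannot estimate C for band ", stack@layerNames[b],
               ": reflectance does not vary with cos(i); supply C")
        Cout[b] <- fit$coefficients[1] / m
      }
    } else Cout[b] <- rep_len(C, nb)[b]
    den <- cosI + Cout[b]
    bad <- abs(den) < tol
    nMasked <- nMasked + sum(bad & ok)
    out <- L * (cos(theta) * cos(alpha) + Cout[b]) / den
    out[bad] <- NA_real_
    vals[, , b] <- out
  }
  if (nMasked > 0)
    warning(nMasked, " pixel(s) masked where cos(i) + C ~ 0")
  names(Cout) <- stack@layerNames
  list(stack = initialize(stack, values = vals), C = Cout, cosI = cosI)
}

.stackFrom <- function(template, layers) {
  vals <- array(unlist(layers, use.names = FALSE),
                dim = c(dim(template@values)[1:2], length(layers)))
  new("BandStack", values = vals, layerNames = names(layers),
      origin = template@origin, cellSize = template@cellSize)
}

#' Band combinations
#'
#' The named ratio / normalized-difference combinations (MVI5, B76, B65,
#' B53, ND563, MVI7) plus four documented extras (B52, B64, B74, ND62)
#' to a set of ten. Zero denominators yield NaN.
#'
#' @param stack a (corrected) [BandStack-class] with layers B1..B7.
#' @param nd563Product logical; evaluate ND563 as the literal product
#'   (B5 + B6 - B3) * (B5 + B6 + B3) instead of the normalized-difference
#'   reading (default `FALSE`).
#' @return a [BandStack-class] of the ten combination layers.
#' @export
bandCombinations <- function(stack, nd563Product = FALSE) {
  B <- lapply(paste0("B", 1:7), function(n) getLayer(stack, n))
  names(B) <- paste0("B", 1:7)
  sdiv <- function(num, den) { r <- num / den; r[den == 0] <- NaN; r }
  layers <- list(
    MVI5 = sdiv(B$B5 + B$B4 - B$B2, B$B5 + B$B4 + B$B2),
    B76 = sdiv(B$B7, B$B6),
    B65 = sdiv(B$B6, B$B5),
    B53 = sdiv(B$B5, B$B3),
    MVI7 = sdiv(B$B5 - B$B7, B$B5 + B$B7),
    ND563 = if (nd563Product) (B$B5 + B$B6 - B$B3) * (B$B5 + B$B6 + B$B3)
            else sdiv(B$B5 + B$B6 - B$B3, B$B5 + B$B6 + B$B3),
    B52 = sdiv(B$B5, B$B2),
    B64 = sdiv(B$B6, B$B4),
    B74 = sdiv(B$B7, B$B4),
    ND62 = sdiv(B$B6 - B$B2, B$B6 + B$B2))
  .stackFrom(stack, layers)
}

#' Vegetation indices
#'
#' Fifteen standard-literature indices (NDVI, EVI, EVI2, ARVI, SAVI,
#' MSAVI, OSAVI, GNDVI, NDMI, NBR2, RVI, DVI, VIG, TVI, NLI) with the
#' canonical coefficient constants. Zero denominators yield NaN.
#'
#' @param stack a (corrected) [BandStack-class] with layers B1..B7.
#' @return a [BandStack-class] of 15 index layers.
#' @export
vegetationIndices <- function(stack) {
  B <- lapply(paste0("B", 1:7), function(n) getLayer(stack, n))
  names(B) <- paste0("B", 1:7)
  sdiv <- function(num, den) { r <- num / den; r[den == 0] <- NaN; r }
  nd <- function(a, b) sdiv(a - b, a + b)
  layers <- list(
    NDVI = nd(B$B5, B$B4),
    EVI = sdiv(2.5 * (B$B5 - B$B4), B$B5 + 6 * B$B4 - 7.5 * B$B2 + 1),
    EVI2 = sdiv(2.5 * (B$B5 - B$B4), B$B5 + 2.4 * B$B4 + 1),
    ARVI = nd(B$B5 - (B$B4 - (B$B2 - B$B4)), B$B5 + (B$B4 - (B$B2 - B$B4))),
    SAVI = sdiv(1.5 * (B$B5 - B$B4), B$B5 + B$B4 + 0.5),
    MSAVI = (2 * B$B5 + 1 -
               sqrt(pmax(0, (2 * B$B5 + 1)^2 - 8 * (B$B5 - B$B4)))) / 2,
    OSAVI = sdiv(B$B5 - B$B4, B$B5 + B$B4 + 0.16),
    GNDVI = nd(B$B5, B$B3),
    NDMI = nd(B$B5, B$B6),
    NBR2 = nd(B$B6, B$B7),
    RVI = sdiv(B$B5, B$B4),
    DVI = B$B5 - B$B4,
    VIG = nd(B$B3, B$B4),
    TVI = 0.5 * (120 * (B$B5 - B$B3) - 200 * (B$B4 - B$B3)),
    NLI = nd(B$B5^2, B$B4))
  .stackFrom(stack, layers)
}

# ARVI above uses rb = B4 - (B2 - B4), i.e. (B5 - rb)/(B5 + rb): simplify
# arguments: B5 - 2*B4 + B2 over B5 + 2*B4 - B2 -- the standard form.

.glcmStatNames <- c("Mean", "Var", "Hom", "Con", "Dis", "Entr", "SM", "Corr")

.glcmOffsets <- function(directions) {
  all <- list("0" = c(0L, 1L), "45" = c(-1L, 1L), "90" = c(-1L, 0L),
              "135" = c(-1L, -1L))
  all[as.character(directions)]
}

# Haralick statistics from co-occurring level pairs (i, j), already
# symmetric, with equal weight per pair entry
.haralickFromPairs <- function(ii, jj, levels) {
  np <- length(ii)
  counts <- tabulate((ii - 1L) * levels + jj, levels * levels)
  p <- counts[counts > 0] / np
  idx <- which(counts > 0)
  i <- ((idx - 1L) %/% levels) + 1L
  j <- ((idx - 1L) %% levels) + 1L
  mu <- sum(p * i)                # symmetric: row and column means equal
  va <- sum(p * (i - mu)^2)
  corr <- if (va < 1e-12) 0 else sum(p * (i - mu) * (j - mu)) / va
  c(Mean = mu, Var = va,
    Hom = sum(p / (1 + (i - j)^2)),
    Con = sum(p * (i - j)^2),
    Dis = sum(p * abs(i - j)),
    Entr = -sum(p * log(p)),
    SM = sum(p^2),
    Corr = corr)
}

#' GLCM (Haralick) texture features of one band
#'
#' Per pixel, grey levels are quantized to `levels` equal bins over the
#' band's unmasked range, the symmetric co-occurrence distribution is
#' accumulated over the requested distance-1 offsets inside a
#' `window` x `window` neighbourhood, and eight Haralick statistics are
#' computed: mean, variance, homogeneity, contrast, dissimilarity,
#' entropy (natural log, 0 log 0 = 0), second moment and correlation
#' (defined as 0 for zero-variance windows). Border pixels without a full
#' window, and windows containing NA, are NA.
#'
#' @param band numeric matrix.
#' @param window odd window size, default 3.
#' @param levels grey levels, default 32.
#' @param directions subset of `c(0, 45, 90, 135)` degree offsets,
#'   default all four (averaged by pooling their pairs).
#' @return named list of eight matrices (`Mean`, `Var`, `Hom`, `Con`,
#'   `Dis`, `Entr`, `SM`, `Corr`).
#' @export
glcmTexture <- function(band, window = 3, levels = 32,
                        directions = c(0, 45, 90, 135)) {
  nr <- nrow(band); nc <- ncol(band)
  if (window > nr || window > nc)
    stop("window exceeds the raster dimensions")
  h <- (window - 1L) %/% 2L
  rng <- range(band, na.rm = TRUE)
  q <- if (diff(rng) == 0) matrix(1L, nr, nc) else {
    qq <- floor((band - rng[1]) / diff(rng) * levels) + 1L
    qq[qq > levels] <- levels
    qq
  }
  offs <- .glcmOffsets(directions)
  out <- lapply(.glcmStatNames, function(s) matrix(NA_real_, nr, nc))
  names(out) <- .glcmStatNames
  # precompute in-window pair index offsets once
  wseq <- seq(-h, h)
  pairIdx <- list()
  for (o in offs) {
    a <- expand.grid(dr = wseq, dc = wseq)
    b <- a
    b$dr <- a$dr + o[1]; b$dc <- a$dc + o[2]
    keep <- abs(b$dr) <= h & abs(b$dc) <= h
    pairIdx[[length(pairIdx) + 1]] <- cbind(a$dr[keep], a$dc[keep],
                                            b$dr[keep], b$dc[keep])
  }
  pairs <- do.call(rbind, pairIdx)
  for (r in seq(h + 1L, nr - h)) {
    for (cc in seq(h + 1L, nc - h)) {
      w <- q[seq(r - h, r + h), seq(cc - h, cc + h), drop = FALSE]
      if (anyNA(band[seq(r - h, r + h), seq(cc - h, cc + h)])) next
      i1 <- w[cbind(pairs[, 1] + h + 1L, pairs[, 2] + h + 1L)]
      i2 <- w[cbind(pairs[, 3] + h + 1L, pairs[, 4] + h + 1L)]
      st <- .haralickFromPairs(c(i1, i2), c(i2, i1), levels)
      for (s in .glcmStatNames) out[[s]][r, cc] <- st[[s]]
    }
  }
  out
}

#' GLCM features for all bands of a stack
#'
#' @param stack a [BandStack-class] with layers B1..B7.
#' @inheritParams glcmTexture
#' @return a [BandStack-class] with 8 x nbands layers named
#'   `<Stat>_<Band>` (e.g. `Entr_B5`).
#' @export
glcmFeatures <- function(stack, window = 3, levels = 32,
                         directions = c(0, 45, 90, 135)) {
  layers <- list()
  for (b in stack@layerNames) {
    tx <- glcmTexture(getLayer(stack, b), window, levels, directions)
    for (s in .glcmStatNames) layers[[paste0(s, "_", b)]] <- tx[[s]]
  }
  .stackFrom(stack, layers)
}

#' Principal components of a band stack
#'
#' Components of the centered pixel x band matrix, ordered by decreasing
#' explained variance, with a deterministic sign convention (the largest
#' absolute loading of each component is made positive). Fewer than the
#' requested components are returned (with a warning) when the band
#' matrix is rank deficient.
#'
#' @param stack a [BandStack-class].
#' @param nComponents number of components, default 3.
#' @return list with `stack` (PC layers), `loadings`, `sdev` and
#'   `explained` (variance shares).
#' @export
pcaTransform <- function(stack, nComponents = 3) {
  d <- dim(stack@values)
  X <- matrix(stack@values, d[1] * d[2], d[3],
              dimnames = list(NULL, stack@layerNames))
  ok <- stats::complete.cases(X)
  pc <- stats::prcomp(X[ok, , drop = FALSE], center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-9)
  if (rank < nComponents) {
    warning("rank ", rank, " < ", nComponents,
            " requested components; returning ", rank)
    nComponents <- rank
  }
  rot <- pc$rotation[, seq_len(nComponents), drop = FALSE]
  flip <- vapply(seq_len(nComponents), function(k) {
    l <- rot[, k]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 0)
  rot <- sweep(rot, 2, flip, `*`)
  scores <- matrix(NA_real_, nrow(X), nComponents)
  scores[ok, ] <- sweep(X[ok, , drop = FALSE], 2, pc$center) %*% rot
  layers <- lapply(seq_len(nComponents), function(k)
    matrix(scores[, k], d[1], d[2]))
  names(layers) <- paste0("PC", seq_len(nComponents))
  list(stack = .stackFrom(stack, layers), loadings = rot, sdev = pc$sdev,
       explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Slope and aspect from a DTM by central finite differences
#'
#' @param dtm a [DtmGrid-class].
#' @return list of matrices `slopeDeg` and `aspectDeg` (downslope
#'   azimuth, degrees clockwise from north).
#' @export
slopeAspect <- function(dtm) {
  e <- dtm@elevation; cs <- dtm@cellSize
  nr <- nrow(e); nc <- ncol(e)
  pad <- function(i, n) pmin(pmax(i, 1), n)
  dzdx <- matrix(0, nr, nc); dzdy <- matrix(0, nr, nc)
  for (cc in seq_len(nc)) {
    c1 <- pad(cc - 1, nc); c2 <- pad(cc + 1, nc)
    dzdx[, cc] <- (e[, c2] - e[, c1]) / ((c2 - c1) * cs)
  }
  for (r in seq_len(nr)) {
    r1 <- pad(r - 1, nr); r2 <- pad(r + 1, nr)
    dzdy[r, ] <- (e[r1, ] - e[r2, ]) / ((r2 - r1) * cs)  # north positive
  }
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  list(slopeDeg = slope, aspectDeg = aspect)
}

#' Sample feature layers at plot locations
#'
#' Default mode takes the pixel containing the plot center; the
#' area-weighted mode averages pixels overlapping the plot rectangle,
#' weighted by overlap area.
#'
#' @param stack a [BandStack-class] of feature layers.
#' @param plots data.frame with `plot_id`, `x`, `y`.
#' @param mode `"center"` or `"area"`.
#' @param plotWidth,plotHeight plot rectangle (m), used by `"area"`.
#' @return data.frame: `plot_id` plus one column per layer.
#' @export
extractPlotFeatures <- function(stack, plots, mode = c("center", "area"),
                                plotWidth = 20, plotHeight = 30) {
  mode <- match.arg(mode)
  d <- dim(stack@values)
  cs <- stack@cellSize
  xmin <- stack@origin[1]; ymin <- stack@origin[2]
  ymax <- ymin + d[1] * cs; xmax <- xmin + d[2] * cs
  out <- matrix(NA_real_, nrow(plots), d[3])
  for (i in seq_len(nrow(plots))) {
    x <- plots$x[i]; y <- plots$y[i]
    if (x < xmin || x >= xmax || y < ymin || y >= ymax)
      stop("plot ", plots$plot_id[i], " lies outside the raster extent")
    if (mode == "center") {
      cc <- floor((x - xmin) / cs) + 1
      r <- d[1] - floor((y - ymin) / cs)
      out[i, ] <- stack@values[r, cc, ]
    } else {
      x0 <- x - plotWidth / 2; x1 <- x + plotWidth / 2
      y0 <- y - plotHeight / 2; y1 <- y + plotHeight / 2
      c0 <- max(1, floor((x0 - xmin) / cs) + 1)
      c1 <- min(d[2], floor((x1 - xmin - 1e-9) / cs) + 1)
      r1 <- min(d[1], d[1] - floor((y0 - ymin) / cs))
      r0 <- max(1, d[1] - floor((y1 - ymin - 1e-9) / cs))
      wsum <- 0; acc <- numeric(d[3])
      for (r in r0:r1) for (cc in c0:c1) {
        cx0 <- xmin + (cc - 1) * cs; cx1 <- cx0 + cs
        cy1 <- ymax - (r - 1) * cs; cy0 <- cy1 - cs
        w <- max(0, min(x1, cx1) - max(x0, cx0)) *
          max(0, min(y1, cy1) - max(y0, cy0))
        if (w > 0) { acc <- acc + w * stack@values[r, cc, ]; wsum <- wsum + w }
      }
      out[i, ] <- acc / wsum
    }
  }
  colnames(out) <- stack@layerNames
  cbind(data.frame(plot_id = plots$plot_id, stringsAsFactors = FALSE),
        as.data.frame(out))
}

#' Derive the full optical feature table for a scene raster
#'
#' Applies SCS+C correction (a no-op factor on flat terrain), derives the
#' original bands, ten band combinations, fifteen vegetation indices,
#' GLCM textures of every band and three principal components, then
#' samples everything at the plot centers: 91 features.
#'
#' @param stack reflectance [BandStack-class] (B1..B7).
#' @param plots data.frame `plot_id`, `x`, `y`.
#' @param slopeDeg,aspectDeg terrain grids or scalars (degrees).
#' @param sunZenithDeg solar zenith angle (degrees), default 44.72
#'   (solar elevation 45.28).
#' @param sunAzimuthDeg solar azimuth, default 154.91.
#' @param mode plot sampling mode, see [extractPlotFeatures()].
#' @return data.frame: `plot_id` + 91 feature columns.
#' @export
opticalFeatureTable <- function(stack, plots, slopeDeg = 0, aspectDeg = 180,
                                sunZenithDeg = 44.72,
                                sunAzimuthDeg = 154.91,
                                mode = "center") {
  corrected <- if (all(slopeDeg == 0)) stack else
    scsCCorrection(stack, slopeDeg, aspectDeg, sunZenithDeg,
                   sunAzimuthDeg)$stack
  pieces <- list(corrected,
                 bandCombinations(corrected),
                 vegetationIndices(corrected),
                 glcmFeatures(corrected),
                 pcaTransform(corrected)$stack)
  tabs <- lapply(pieces, extractPlotFeatures, plots = plots, mode = mode)
  out <- Reduce(function(a, b) merge(a, b, by = "plot_id", sort = FALSE),
                tabs)
  out[order(out$plot_id), , drop = FALSE]
}
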
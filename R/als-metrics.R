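# Point-cloud preprocessing (plane-fit noise removal, IDW terrain model,
# height normalization) and the plot-level ALS metric families: canopy /
# forest metrics, elevation statistics and percentiles, height-interval
# density deciles, and intensity statistics including height-ordered
# cumulative-intensity (AII) proportions.
#
# Percentile convention: linear interpolation between closest ranks
# (R quantile type 7), pinned and documented; the AII_k metrics take the
# lowest k% of above-threshold returns *by height* (ceiling count), an
# intensity-ordered variant is available behind `aiiOrder = "intensity"`.

.percGrid <- c(1, seq(5, 95, by = 5), 99)

#' Remove isolated noise returns by local plane fitting
#'
#' For every return, a least-squares plane is fitted to its neighbours
#' within `radius` (3-d distance). The return is kept iff its distance to
#' that plane is at most `max(sdMultiplier * SD, eps)` where SD is the
#' standard deviation of the neighbours' plane distances (the `eps` floor
#' keeps exactly coplanar neighbourhoods, whose SD is 0). Returns with
#' fewer than 3 neighbours are kept (insufficient plane support) with a
#' warning. Flagged returns are re-classified `"noise"`.
#'
#' @param cloud a [LidarCloud-class]
#' @param radius neighbourhood radius (m), default 0.5.
#' @param sdMultiplier SD multiple, default 1.
#' @param eps tie tolerance for degenerate (zero-SD) planes.
#' @return the cloud with noise returns re-classified.
#' @export
removeNoise <- function(cloud, radius = 0.5, sdMultiplier = 1, eps = 1e-8) {
  p <- cloudPoints(cloud)
  n <- nrow(p)
  if (n == 0) stop("cloud is empty")
  keep <- rep(TRUE, n)
  unsupported <- 0L
  xyz <- as.matrix(p[, c("x", "y", "z")])
  for (i in seq_len(n)) {
    # horizontal neighbourhood: air/low points sit far from the local
    # surface fitted through the returns around their (x, y) position
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2
    nb <- which(d2 <= radius^2 & seq_len(n) != i)
    if (length(nb) < 3) { unsupported <- unsupported + 1L; next }
    A <- cbind(1, xyz[nb, 1], xyz[nb, 2])
    fit <- stats::lm.fit(A, xyz[nb, 3])
    co <- fit$coefficients
    co[is.na(co)] <- 0
    denom <- sqrt(1 + co[2]^2 + co[3]^2)
    resNb <- fit$residuals / denom
    di <- abs(xyz[i, 3] - (co[1] + co[2] * xyz[i, 1] + co[3] * xyz[i, 2])) /
      denom
    keep[i] <- di <= max(sdMultiplier * stats::sd(resNb), eps)
  }
  if (unsupported > 0)
    warning(unsupported, " return(s) kept with fewer than 3 neighbours ",
            "within ", radius, " m")
  p$classification[!keep] <- "noise"
  initialize(cloud, points = p)
}

.gridGeom <- function(origin, cellSize, nr, nc) {
  list(xmin = origin[1], ymin = origin[2],
       xmax = origin[1] + nc * cellSize, ymax = origin[2] + nr * cellSize)
}

#' Interpolate a DTM from ground returns by inverse-distance weighting
#'
#' Each cell value is the IDW mean of the `k` nearest ground returns with
#' weights d^-power; a cell whose center coincides with a ground return
#' (distance < 1e-9) takes that return's elevation exactly.
#'
#' @param cloud a [LidarCloud-class] (its `"ground"`-classified returns
#'   are used) or a data.frame with columns x, y, z of ground points.
#' @param cellSize grid resolution (m), default 0.5.
#' @param power IDW distance exponent, default 2.
#' @param k number of nearest ground points per cell, default 12 (capped
#'   at the number of ground points).
#' @return a [DtmGrid-class] covering the ground-point bounding box.
#' @export
interpolateDtmIdw <- function(cloud, cellSize = 0.5, power = 2, k = 12) {
  g <- if (is(cloud, "LidarCloud")) {
    p <- cloudPoints(cloud)
    p[p$classification == "ground", c("x", "y", "z")]
  } else cloud[, c("x", "y", "z")]
  if (nrow(g) == 0) stop("no ground returns")
  k <- min(k, nrow(g))
  xmin <- floor(min(g$x) / cellSize) * cellSize
  ymin <- floor(min(g$y) / cellSize) * cellSize
  nc <- max(1L, ceiling((max(g$x) - xmin) / cellSize))
  nr <- max(1L, ceiling((max(g$y) - ymin) / cellSize))
  cx <- xmin + (seq_len(nc) - 0.5) * cellSize
  cy <- ymin + (nr - seq_len(nr) + 0.5) * cellSize  # row 1 = north
  elev <- matrix(NA_real_, nr, nc)
  gx <- g$x; gy <- g$y; gz <- g$z
  for (r in seq_len(nr)) {
    dy2 <- (gy - cy[r])^2
    for (cc in seq_len(nc)) {
      d2 <- (gx - cx[cc])^2 + dy2
      nb <- order(d2)[seq_len(k)]
      d <- sqrt(d2[nb])
      if (d[1] < 1e-9) { elev[r, cc] <- gz[nb[1]]; next }
      w <- d^(-power)
      elev[r, cc] <- sum(w * gz[nb]) / sum(w)
    }
  }
  new("DtmGrid", elevation = elev, origin = c(xmin, ymin),
      cellSize = cellSize)
}

# bilinear sample of a north-up grid at (x, y); coordinates are clamped
# to the outermost cell centers so edge points stay defined
.bilinear <- function(dtm, x, y) {
  e <- dtm@elevation; cs <- dtm@cellSize
  nr <- nrow(e); nc <- ncol(e)
  fx <- (x - dtm@origin[1]) / cs - 0.5
  fy <- (dtm@origin[2] + nr * cs - y) / cs - 0.5  # row coordinate
  fx <- pmin(pmax(fx, 0), nc - 1)
  fy <- pmin(pmax(fy, 0), nr - 1)
  c0 <- pmin(floor(fx), nc - 2 + (nc == 1)); r0 <- pmin(floor(fy), nr - 2 + (nr == 1))
  c0 <- pmax(c0, 0); r0 <- pmax(r0, 0)
  tx <- fx - c0; ty <- fy - r0
  i00 <- cbind(r0 + 1, c0 + 1)
  i01 <- cbind(r0 + 1, pmin(c0 + 2, nc))
  i10 <- cbind(pmin(r0 + 2, nr), c0 + 1)
  i11 <- cbind(pmin(r0 + 2, nr), pmin(c0 + 2, nc))
  (1 - ty) * ((1 - tx) * e[i00] + tx * e[i01]) +
    ty * ((1 - tx) * e[i10] + tx * e[i11])
}

#' Normalize return heights against a DTM
#'
#' Replaces z by z minus the bilinearly sampled DTM elevation, so ground
#' returns sit near height 0. Points outside the DTM extent are an error.
#'
#' @param cloud a [LidarCloud-class]
#' @param dtm a [DtmGrid-class]
#' @return the height-normalized cloud (`normalized = TRUE`).
#' @export
normalizeHeights <- function(cloud, dtm) {
  p <- cloudPoints(cloud)
  if (nrow(p) == 0) return(initialize(cloud, normalized = TRUE))
  g <- .gridGeom(dtm@origin, dtm@cellSize, nrow(dtm@elevation),
                 ncol(dtm@elevation))
  out <- p$x < g$xmin | p$x > g$xmax | p$y < g$ymin | p$y > g$ymax
  if (any(out))
    stop(sum(out), " point(s) fall outside the DTM extent")
  p$z <- p$z - .bilinear(dtm, p$x, p$y)
  initialize(cloud, points = p, normalized = TRUE)
}

.activePoints <- function(cloud) {
  p <- cloudPoints(cloud)
  p[p$classification != "noise", , drop = FALSE]
}

.nanMetrics <- function(names) setNames(rep(NaN, length(names)), names)

.elevNames <- function() {
  c("elev_mean", "elev_sd", "elev_cv", "elev_var", "elev_skew",
    "elev_kurt", "elev_min", "elev_max", "elev_aad", "elev_mad",
    "elev_sqmean", "elev_crr", "elev_iq",
    paste0("elev_per_", .percGrid, "th"))
}

#' Elevation (height) metrics of a normalized cloud
#'
#' Over non-noise returns at or above `heightThreshold`: mean, SD, CV,
#' variance, skewness, kurtosis, min, max, average absolute deviation,
#' median absolute deviation, quadratic mean, canopy relief ratio,
#' interquartile range and the 1, 5, 10..95, 99 height percentiles
#' (linear-interpolation convention).
#'
#' @param cloud a height-normalized [LidarCloud-class]
#' @param heightThreshold metric cutoff (m), default 2 (matching the
#'   gap-fraction threshold).
#' @return named numeric vector; all-NaN with a warning when no return
#'   reaches the threshold.
#' @export
elevationMetrics <- function(cloud, heightThreshold = 2) {
  z <- .activePoints(cloud)$z
  z <- z[z >= heightThreshold]
  nm <- .elevNames()
  if (length(z) == 0) {
    warning("no returns above the height threshold; elevation metrics NaN")
    return(.nanMetrics(nm))
  }
  q <- stats::quantile(z, .percGrid / 100, type = 7, names = FALSE)
  m <- mean(z)
  out <- c(m, stats::sd(z), stats::sd(z) / m, stats::var(z),
           if (length(z) > 2) e1071::skewness(z) else NaN,
           if (length(z) > 3) e1071::kurtosis(z) else NaN,
           min(z), max(z), mean(abs(z - m)),
           stats::median(abs(z - stats::median(z))), sqrt(mean(z^2)),
           if (max(z) > min(z)) (m - min(z)) / (max(z) - min(z)) else NaN,
           q[16] - q[6],  # p75 - p25
           q)
  if (length(z) == 1) out[c(2, 3, 4)] <- NaN
  setNames(out, nm)
}

#' Height-interval density metrics
#'
#' The span from `heightThreshold` to the maximum height is split into
#' `nIntervals` equal slices; `density_i` is the fraction of
#' above-threshold returns in slice i (top slice closed above). A
#' degenerate span (max height equal to the threshold) puts all mass in
#' slice 1.
#'
#' @inheritParams elevationMetrics
#' @param nIntervals number of slices, default 10.
#' @return named numeric vector `density_1 .. density_n` summing to 1
#'   (all NaN with a warning when no return reaches the threshold).
#' @export
densityMetrics <- function(cloud, nIntervals = 10, heightThreshold = 2) {
  z <- .activePoints(cloud)$z
  z <- z[z >= heightThreshold]
  nm <- paste0("density_", seq_len(nIntervals))
  if (length(z) == 0) {
    warning("no returns above the height threshold; density metrics NaN")
    return(.nanMetrics(nm))
  }
  span <- max(z) - heightThreshold
  if (span <= 0) {
    out <- c(1, rep(0, nIntervals - 1))
    return(setNames(out, nm))
  }
  idx <- pmin(floor((z - heightThreshold) / span * nIntervals) + 1,
              nIntervals)
  setNames(tabulate(idx, nIntervals) / length(z), nm)
}

.intNames <- function(aii = TRUE) {
  c("int_max", "int_mean", "int_sd", "int_cv", "int_skew", "int_kurt",
    "int_min", paste0("int_per_", .percGrid, "th"),
    if (aii) paste0("int_AII_", .percGrid, "th"))
}

#' Intensity metrics
#'
#' Over non-noise returns at or above `heightThreshold`: max, mean, SD,
#' CV, skewness, kurtosis, min and the intensity percentiles, plus the
#' cumulative-intensity proportions `int_AII_k`: the summed intensity of
#' the lowest (by height, default) ceiling(k% * n) returns divided by the
#' total intensity.
#'
#' @inheritParams elevationMetrics
#' @param aiiOrder `"height"` (default; lowest k% of returns by height)
#'   or `"intensity"` (lowest k% by intensity).
#' @return named numeric vector; AII metrics are NaN with a warning when
#'   the total intensity is 0.
#' @export
intensityMetrics <- function(cloud, heightThreshold = 2,
                             aiiOrder = c("height", "intensity")) {
  aiiOrder <- match.arg(aiiOrder)
  p <- .activePoints(cloud)
  p <- p[p$z >= heightThreshold, , drop = FALSE]
  nm <- .intNames()
  if (nrow(p) == 0) {
    warning("no returns above the height threshold; intensity metrics NaN")
    return(.nanMetrics(nm))
  }
  i <- p$intensity
  q <- stats::quantile(i, .percGrid / 100, type = 7, names = FALSE)
  m <- mean(i)
  base <- c(max(i), m, stats::sd(i), stats::sd(i) / m,
            if (length(i) > 2) e1071::skewness(i) else NaN,
            if (length(i) > 3) e1071::kurtosis(i) else NaN, min(i), q)
  tot <- sum(i)
  if (tot == 0) {
    warning("total intensity is 0; AII metrics NaN")
    aii <- rep(NaN, length(.percGrid))
  } else {
    ord <- if (aiiOrder == "height") order(p$z) else order(i)
    cum <- cumsum(i[ord])
    counts <- ceiling(.percGrid / 100 * length(i))
    aii <- cum[counts] / tot
  }
  setNames(c(base, aii), nm)
}

#' Canopy (forest) metrics
#'
#' `gap_fraction` = share of all returns below the height threshold;
#' `canopy_cover` = share of first returns at or above it; `lai` =
#' -cos(scan angle) * log(gap_fraction) / extinction coefficient
#' (Beer-Lambert inversion; scan angle assumed nadir).
#'
#' @inheritParams elevationMetrics
#' @param extinctionK extinction coefficient, default 0.5.
#' @param scanAngle mean scan angle in radians, default 0 (nadir).
#' @return named numeric vector `gap_fraction`, `canopy_cover`, `lai`.
#'   `lai` is NaN with a warning when the gap fraction is 0;
#'   `canopy_cover` is NaN when there are no first returns.
#' @export
forestMetrics <- function(cloud, heightThreshold = 2, extinctionK = 0.5,
                          scanAngle = 0) {
  p <- .activePoints(cloud)
  if (nrow(p) == 0)
    return(.nanMetrics(c("gap_fraction", "canopy_cover", "lai")))
  gap <- sum(p$z < heightThreshold) / nrow(p)
  first <- p$return_number == 1
  cover <- if (any(first)) {
    sum(first & p$z >= heightThreshold) / sum(first)
  } else {
    warning("no first returns; canopy_cover NaN")
    NaN
  }
  lai <- if (gap == 0) {
    warning("gap fraction 0; LAI unbounded, reported NaN")
    NaN
  } else -cos(scanAngle) * log(gap) / extinctionK
  c(gap_fraction = gap, canopy_cover = cover, lai = lai)
}

#' Clip a cloud to an axis-aligned plot rectangle
#'
#' Half-open edges: x in [cx - w/2, cx + w/2), y likewise.
#'
#' @param cloud a [LidarCloud-class]
#' @param center plot center `c(x, y)`.
#' @param width,height rectangle dimensions (m).
#' @return the clipped [LidarCloud-class].
#' @export
clipPlot <- function(cloud, center, width = 20, height = 30) {
  p <- cloudPoints(cloud)
  keep <- p$x >= center[1] - width / 2 & p$x < center[1] + width / 2 &
    p$y >= center[2] - height / 2 & p$y < center[2] + height / 2
  initialize(cloud, points = p[keep, , drop = FALSE])
}

#' Fallback ground classification (NOT a progressive TIN filter)
#'
#' A deliberately simple lowest-point-grid rule for clouds that arrive
#' without ground labels: within each `cellSize` grid cell, returns within
#' `tol` of the cell's lowest return are classed ground. The synthetic
#' generator labels ground returns itself; this helper only serves
#' unlabeled external clouds and is not the progressive densification
#' filter used in operational processing chains.
#'
#' @param cloud a [LidarCloud-class]
#' @param cellSize grid cell (m), default 5.
#' @param tol height tolerance above the cell minimum (m), default 0.3.
#' @return the cloud with `classification` rewritten (ground / nonground).
#' @export
classifyGroundSimple <- function(cloud, cellSize = 5, tol = 0.3) {
  p <- cloudPoints(cloud)
  if (nrow(p) == 0) return(cloud)
  key <- paste(floor(p$x / cellSize), floor(p$y / cellSize))
  zmin <- stats::ave(p$z, key, FUN = min)
  cls <- ifelse(p$z <= zmin + tol, "ground", "nonground")
  cls[p$classification == "noise"] <- "noise"
  p$classification <- cls
  initialize(cloud, points = p)
}

#' Extract the full ALS metric table for a set of plots
#'
#' Computes the forest, elevation, density and intensity families for
#' each plot cloud and binds them into one feature table with a stable
#' column order. A failing plot yields an all-NaN row plus a warning, not
#' an error.
#'
#' @param clouds named list of height-normalized [LidarCloud-class]
#'   objects (names are plot ids).
#' @param heightThreshold metric cutoff (m), default 2.
#' @param nIntervals density slices, default 10.
#' @return data.frame: `plot_id` plus all metric columns, sorted by
#'   plot_id.
#' @export
extractAlsMetrics <- function(clouds, heightThreshold = 2, nIntervals = 10) {
  nm <- c("gap_fraction", "canopy_cover", "lai", .elevNames(),
          paste0("density_", seq_len(nIntervals)), .intNames())
  if (length(clouds) == 0) {
    empty <- as.data.frame(matrix(numeric(), 0, length(nm),
                                  dimnames = list(NULL, nm)))
    return(cbind(plot_id = character(), empty, stringsAsFactors = FALSE))
  }
  rows <- lapply(names(clouds), function(id) {
    vals <- tryCatch(
      suppressWarnings(c(forestMetrics(clouds[[id]], heightThreshold),
                         elevationMetrics(clouds[[id]], heightThreshold),
                         densityMetrics(clouds[[id]], nIntervals,
                                        heightThreshold),
                         intensityMetrics(clouds[[id]], heightThreshold))),
      error = function(e) {
        warning("plot ", id, " failed: ", conditionMessage(e))
        .nanMetrics(nm)
      })
    vals[nm]
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- nm
  tab <- cbind(plot_id = names(clouds), tab, stringsAsFactors = FALSE)
  tab <- tab[order(tab$plot_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
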
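# Synthetic forest scenes with known generative parameters: plot tree
# lists (species + DBH), per-plot ALS point clouds whose height structure
# follows the plot AGB, and a multiband reflectance raster with a
# saturating AGB response. Every stochastic draw flows from the master
# seed through named per-plot substreams, so adding plots never perturbs
# earlier ones.

.subSeed <- function(seed, plotIndex, stream) {
  as.integer((as.numeric(seed) + 1000003 * plotIndex + 7919 * stream) %%
               2147483629L)
}

.defaultBandParams <- function() {
  # r0 + r1*exp(-AGB/s): visible and SWIR bands darken with biomass, NIR
  # (band 5) brightens (negative r1); s = saturation scale in Mg/ha, in
  # the range reported for temperate/subtropical mixed forests.
  m <- rbind(B1 = c(0.020, 0.050, 60),
             B2 = c(0.030, 0.060, 60),
             B3 = c(0.050, 0.050, 70),
             B4 = c(0.030, 0.090, 60),
             B5 = c(0.350, -0.150, 90),
             B6 = c(0.100, 0.120, 80),
             B7 = c(0.060, 0.100, 70))
  colnames(m) <- c("r0", "r1", "s")
  m
}

.defaultSpeciesMix <- function() {
  c("Betula platyphylla" = 0.30, "Quercus mongolica" = 0.22,
    "Populus davidiana" = 0.14, "Fraxinus mandshurica" = 0.10,
    "Acer mono" = 0.08, "Tilia mongolica" = 0.06,
    "Larix olgensis" = 0.06, "Pinus koraiensis" = 0.04)
}

#' Build a scene configuration
#'
#' Constructor with defaults emulating the study conditions of a
#' temperate natural secondary forest inventory: 20 m x 30 m plots, ALS
#' density 3.6 points/m^2, mixed broadleaf-dominated species composition,
#' and seven reflectance bands saturating in AGB.
#'
#' @param nPlots number of plots.
#' @param plotWidth,plotHeight plot size (m).
#' @param pointDensity returns per m^2.
#' @param stemsLambda Poisson mean stems (DBH >= 5 cm) per plot.
#' @param speciesMix named proportions (must sum to 1; names must be
#'   species of [allometryTable()]).
#' @param dbhWeibull named list of `c(shape, scale)` DBH Weibull
#'   parameters per species; the `"default"` entry covers the rest.
#' @param h0,gamma canopy top height H = h0 * AGB^gamma.
#' @param groundFraction expected ground-return fraction.
#' @param bandParams 7 x 3 matrix (r0, r1, s) of the reflectance model.
#' @param bandNoiseSd per-band reflectance noise SD (length 1 or 7).
#' @param zNoiseSd,intensityI0,intensityK,intensityNoiseSd point-cloud
#'   noise and intensity-model parameters.
#' @param slopeDeg,aspectDeg planar terrain slope/aspect (degrees).
#' @param seed master seed.
#' @return a [SceneConfig-class]
#' @examples
#' cfg <- sceneConfig(nPlots = 4, seed = 1)
#' cfg
#' @export
sceneConfig <- function(nPlots, plotWidth = 20, plotHeight = 30,
                        pointDensity = 3.6, stemsLambda = 60,
                        speciesMix = .defaultSpeciesMix(),
                        dbhWeibull = list(default = c(shape = 2, scale = 15)),
                        h0 = 1.6, gamma = 0.5, groundFraction = 0.25,
                        bandParams = .defaultBandParams(),
                        bandNoiseSd = 0.01, zNoiseSd = 0.15,
                        intensityI0 = 1000, intensityK = 0.3,
                        intensityNoiseSd = 10, slopeDeg = 0, aspectDeg = 180,
                        seed = 1L) {
  known <- allometryTable()$species
  bad <- setdiff(names(speciesMix), known)
  if (length(bad))
    stop("speciesMix names not in the allometric table: ",
         paste(bad, collapse = ", "))
  new("SceneConfig", nPlots = as.integer(nPlots), plotWidth = plotWidth,
      plotHeight = plotHeight, pointDensity = pointDensity,
      stemsLambda = stemsLambda, speciesMix = speciesMix,
      dbhWeibull = dbhWeibull, h0 = h0, gamma = gamma,
      groundFraction = groundFraction, bandParams = bandParams,
      bandNoiseSd = rep_len(bandNoiseSd, 7), zNoiseSd = zNoiseSd,
      intensityI0 = intensityI0, intensityK = intensityK,
      intensityNoiseSd = intensityNoiseSd, slopeDeg = slopeDeg,
      aspectDeg = aspectDeg, seed = as.integer(seed))
}

.weibullPars <- function(cfg, species) {
  p <- cfg@dbhWeibull[[species]]
  if (is.null(p)) p <- cfg@dbhWeibull[["default"]]
  if (is.null(p)) stop("no DBH Weibull parameters for ", species,
                       " and no default entry")
  p
}

# inverse-CDF draw from Weibull(shape, scale) truncated below at `lower`
.rtruncWeibull <- function(n, shape, scale, lower = 5) {
  pLo <- stats::pweibull(lower, shape, scale)
  u <- stats::runif(n, pLo, 1)
  stats::qweibull(u, shape, scale)
}

#' Generate a plot tree list
#'
#' Stem count ~ Poisson(stemsLambda); species drawn from the mixing
#' proportions; DBH drawn from the species Weibull truncated at the 5 cm
#' census threshold.
#'
#' @param cfg a [SceneConfig-class]
#' @param plotIndex 1-based plot index (selects the seeded substream).
#' @param plotId plot identifier stored in the output.
#' @return data.frame with columns `plot_id`, `species`, `dbh_cm`.
#' @export
generateTreeList <- function(cfg, plotIndex,
                             plotId = sprintf("plot_%03d", plotIndex)) {
  set.seed(.subSeed(cfg@seed, plotIndex, 1L))
  n <- stats::rpois(1, cfg@stemsLambda)
  if (n == 0)
    return(data.frame(plot_id = character(), species = character(),
                      dbh_cm = numeric(), stringsAsFactors = FALSE))
  sp <- sample(names(cfg@speciesMix), n, replace = TRUE,
               prob = cfg@speciesMix)
  dbh <- numeric(n)
  for (s in unique(sp)) {
    p <- .weibullPars(cfg, s)
    dbh[sp == s] <- .rtruncWeibull(sum(sp == s), p[1], p[2])
  }
  data.frame(plot_id = plotId, species = sp, dbh_cm = dbh,
             stringsAsFactors = FALSE)
}

.terrainElev <- function(cfg, x, y, base = 100) {
  if (cfg@slopeDeg == 0) return(rep(base, length(x)))
  az <- cfg@aspectDeg * pi / 180  # downslope azimuth
  base - tan(cfg@slopeDeg * pi / 180) * (sin(az) * x + cos(az) * y)
}

#' Simulate an ALS point cloud for one plot
#'
#' Return count ~ Poisson(density x area). Non-ground heights follow a
#' Beta(2, 1.2) canopy profile scaled to the top height
#' H = h0 * AGB^gamma; a configured fraction of returns are ground hits
#' near height 0; intensity decays exponentially with depth into the
#' canopy. A plot with AGB = 0 yields only ground returns.
#'
#' @param cfg a [SceneConfig-class]
#' @param agb true plot AGB density (Mg/ha), >= 0.
#' @param center plot center `c(x, y)` in scene coordinates (m).
#' @param plotIndex 1-based index selecting the seeded substream.
#' @return a [LidarCloud-class] with raw (terrain-referenced) elevations.
#' @export
simulatePointCloud <- function(cfg, agb, center = c(0, 0), plotIndex = 1L) {
  if (agb < 0) stop("agb must be >= 0")
  set.seed(.subSeed(cfg@seed, plotIndex, 2L))
  area <- cfg@plotWidth * cfg@plotHeight
  n <- stats::rpois(1, cfg@pointDensity * area)
  if (n == 0) return(new("LidarCloud"))
  x <- center[1] + stats::runif(n, -cfg@plotWidth / 2, cfg@plotWidth / 2)
  y <- center[2] + stats::runif(n, -cfg@plotHeight / 2, cfg@plotHeight / 2)
  H <- cfg@h0 * agb^cfg@gamma
  ground <- if (agb == 0) rep(TRUE, n) else
    stats::runif(n) < cfg@groundFraction
  height <- numeric(n)
  ng <- !ground
  if (any(ng)) height[ng] <- H * stats::rbeta(sum(ng), 2, 1.2)
  z <- .terrainElev(cfg, x, y) + height +
    stats::rnorm(n, 0, cfg@zNoiseSd)
  depth <- ifelse(ground & agb > 0, H, H - height)
  intensity <- pmax(0, cfg@intensityI0 * exp(-cfg@intensityK * depth) +
                       stats::rnorm(n, 0, cfg@intensityNoiseSd))
  p1 <- ifelse(ground, ifelse(agb > 0, 0.3, 1),
               0.5 + 0.5 * height / max(H, 1e-9))
  rn <- ifelse(stats::runif(n) < p1, 1L,
               1L + sample(1:2, n, replace = TRUE))
  new("LidarCloud",
      points = data.frame(x = x, y = y, z = z, intensity = intensity,
                          return_number = as.integer(rn),
                          classification = ifelse(ground, "ground",
                                                  "nonground"),
                          stringsAsFactors = FALSE),
      normalized = FALSE)
}

#' Simulate saturating band reflectance for AGB values
#'
#' Band b = r0_b + r1_b * exp(-AGB / s_b) + Gaussian noise, clipped to
#' the unit reflectance interval. The exponential makes reflectance
#' insensitive to biomass change above the band's saturation scale s_b.
#'
#' @param cfg a [SceneConfig-class]
#' @param agb numeric vector of AGB (Mg/ha), >= 0.
#' @param seed substream seed (default derived from the config seed).
#' @param noise logical; set `FALSE` for the noiseless expectation.
#' @return matrix `length(agb)` x 7, columns B1..B7.
#' @export
simulateReflectance <- function(cfg, agb, seed = .subSeed(cfg@seed, 0L, 3L),
                                noise = TRUE) {
  if (any(agb < 0)) stop("agb must be >= 0")
  set.seed(seed)
  bp <- cfg@bandParams
  r <- outer(agb, seq_len(7), function(a, b)
    bp[b, 1] + bp[b, 2] * exp(-a / bp[b, 3]))
  if (noise && any(cfg@bandNoiseSd > 0))
    r <- r + matrix(stats::rnorm(length(r), 0,
                                 rep(cfg@bandNoiseSd, each = length(agb))),
                    nrow = length(agb))
  r[] <- pmin(1, pmax(0, r))
  colnames(r) <- paste0("B", 1:7)
  r
}

#' Build a complete synthetic scene
#'
#' Lays plots on a non-overlapping grid (90 m spacing, three 30 m raster
#' cells, so each plot center falls in its own pixel), generates tree
#' lists, computes ground-truth AGB through the allometry module, draws
#' one point cloud per plot, and fills a seven-band 30 m reflectance
#' raster. Raster pixels that contain a plot center take that plot's true
#' AGB as the latent value; other pixels draw a latent AGB by resampling
#' the plot AGB distribution with multiplicative jitter.
#'
#' @param cfg a [SceneConfig-class]
#' @return list with elements `config`, `plots` (plot_id, x, y), `trees`,
#'   `truth` (plot_id, agb_mg_ha, top_height_m), `clouds` (named list of
#'   [LidarCloud-class]), `raster` ([BandStack-class] B1..B7),
#'   `latentAgb` (matrix of the per-pixel latent AGB), `slopeDeg`,
#'   `aspectDeg`.
#' @examples
#' sc <- buildScene(sceneConfig(nPlots = 2, seed = 7))
#' sc$truth
#' @export
buildScene <- function(cfg) {
  n <- cfg@nPlots
  gc <- max(1L, ceiling(sqrt(n)))
  gr <- max(1L, ceiling(n / gc))
  spacing <- 90
  ids <- if (n) sprintf("plot_%03d", seq_len(n)) else character()
  px <- (((seq_len(n) - 1) %% gc)) * spacing + spacing / 2
  py <- (((seq_len(n) - 1) %/% gc)) * spacing + spacing / 2
  plots <- data.frame(plot_id = ids, x = px, y = py,
                      stringsAsFactors = FALSE)

  trees <- do.call(rbind, c(list(
    data.frame(plot_id = character(), species = character(),
               dbh_cm = numeric(), stringsAsFactors = FALSE)),
    lapply(seq_len(n), function(i) generateTreeList(cfg, i, ids[i]))))
  areaHa <- cfg@plotWidth * cfg@plotHeight / 1e4
  agb <- setNames(rep(0, n), ids)
  if (nrow(trees)) {
    dens <- plotAgbDensity(trees, plotArea = areaHa)
    agb[dens$plot_id] <- dens$agb_mg_ha
  }
  truth <- data.frame(plot_id = ids, agb_mg_ha = unname(agb),
                      top_height_m = cfg@h0 * unname(agb)^cfg@gamma,
                      stringsAsFactors = FALSE)

  clouds <- lapply(seq_len(n), function(i)
    simulatePointCloud(cfg, agb[i], center = c(px[i], py[i]),
                       plotIndex = i))
  names(clouds) <- ids

  nrR <- 3L * gr; ncR <- 3L * gc
  cell <- 30
  set.seed(.subSeed(cfg@seed, 0L, 4L))
  latent <- matrix(if (n) sample(unname(agb), nrR * ncR, replace = TRUE) *
                     stats::runif(nrR * ncR, 0.6, 1.4) else 0, nrR, ncR)
  # pixel indices of plot centers (row 1 = north = max y)
  if (n) {
    colIdx <- floor(px / cell) + 1
    rowIdx <- nrR - floor(py / cell)
    latent[cbind(rowIdx, colIdx)] <- unname(agb)
  }
  refl <- simulateReflectance(cfg, as.vector(latent),
                              seed = .subSeed(cfg@seed, 0L, 5L))
  vals <- array(refl, dim = c(nrR, ncR, 7),
                dimnames = list(NULL, NULL, colnames(refl)))
  raster <- new("BandStack", values = vals, layerNames = colnames(refl),
                origin = c(0, 0), cellSize = cell)
  if (n && (max(px) >= ncR * cell || max(py) >= nrR * cell))
    stop("plot layout exceeds the raster extent")

  list(config = cfg, plots = plots, trees = trees, truth = truth,
       clouds = clouds, raster = raster, latentAgb = latent,
       slopeDeg = cfg@slopeDeg, aspectDeg = cfg@aspectDeg)
}

#' Write a scene to plain-text files
#'
#' Writes `plots.csv`, `trees.csv`, `truth.csv`, one `cloud_<plot>.csv`
#' per plot and a long-format `raster.csv` (row, col, band, value).
#'
#' @param scene result of [buildScene()]
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(scene$plots, file.path(dir, "plots.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$trees, file.path(dir, "trees.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  for (id in names(scene$clouds))
    utils::write.csv(cloudPoints(scene$clouds[[id]]),
                     file.path(dir, paste0("cloud_", id, ".csv")),
                     row.names = FALSE)
  v <- scene$raster@values
  long <- do.call(rbind, lapply(seq_len(dim(v)[3]), function(b)
    data.frame(row = rep(seq_len(dim(v)[1]), dim(v)[2]),
               col = rep(seq_len(dim(v)[2]), each = dim(v)[1]),
               band = layerNames(scene$raster)[b],
               value = as.vector(v[, , b]))))
  utils::write.csv(long, file.path(dir, "raster.csv"), row.names = FALSE)
  invisible(dir)
}
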
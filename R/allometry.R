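# Species-specific allometric power laws W = a * D^b for the major tree
# and understory species of the temperate natural secondary forests of
# northeastern China. One row of the coefficient table covers the three
# species Fraxinus mandshurica / Juglans mandshurica / Phellodendron
# amurense, which share a published (a, b) pair; it is registered under
# all three names. Plantation variants carry the "_plantation" suffix and
# must be requested explicitly.

.ALLOMETRY <- local({
  tab <- rbind(
    c("Acer mono",                    "deciduous",  "natural",    0.318, 2.081),
    c("Ulmus pumila",                 "deciduous",  "natural",    0.350, 1.995),
    c("Populus davidiana",            "deciduous",  "natural",    0.078, 2.512),
    c("Betula platyphylla",           "deciduous",  "natural",    0.313, 2.114),
    c("Quercus mongolica",            "deciduous",  "natural",    0.097, 2.501),
    c("Tilia mongolica",              "deciduous",  "natural",    0.083, 2.422),
    c("Fraxinus mandshurica",         "deciduous",  "natural",    0.268, 2.118),
    c("Juglans mandshurica",          "deciduous",  "natural",    0.268, 2.118),
    c("Phellodendron amurense",       "deciduous",  "natural",    0.268, 2.118),
    c("Larix olgensis",               "coniferous", "natural",    0.168, 2.248),
    c("Pinus koraiensis",             "coniferous", "natural",    0.082, 2.426),
    c("Picea asperata",               "coniferous", "natural",    0.067, 2.517),
    c("Larix olgensis_plantation",    "coniferous", "plantation", 0.222, 2.174),
    c("Pinus koraiensis_plantation",  "coniferous", "plantation", 0.206, 2.117),
    c("Pinus sylvestris_plantation",  "coniferous", "plantation", 0.080, 2.440),
    c("Acer ginnala",                 "understory", "understory", 0.527, 2.217),
    c("Syringa reticulata",           "understory", "understory", 0.395, 2.300),
    c("Padus asiatica",               "understory", "understory", 0.090, 2.696),
    c("Rhamnus yoshinoi",             "understory", "understory", 0.169, 2.555),
    c("Arbor-like mixed species",     "understory", "understory", 0.182, 2.487))
  data.frame(species = tab[, 1], group = tab[, 2], origin = tab[, 3],
             a = as.numeric(tab[, 4]), b = as.numeric(tab[, 5]),
             stringsAsFactors = FALSE)
})

#' Allometric coefficient table
#'
#' The packaged species-specific coefficients of the power law
#' W = a * D^b (W in kg, D = DBH in cm) for northeastern-China natural
#' secondary forest species: deciduous and coniferous overstory species
#' (natural stands plus three plantation variants) and understory species,
#' including an "Arbor-like mixed species" understory catch-all. The three
#' species sharing one published coefficient pair appear as three rows
#' with identical `a` and `b`.
#'
#' @param includeUnderstory logical; keep the understory rows (default
#'   `TRUE`; the plot census covers trees with DBH >= 5 cm, so understory
#'   equations are normally not applied to plot totals).
#' @return data.frame with columns `species`, `group`, `origin`, `a`, `b`.
#' @examples
#' head(allometryTable())
#' @export
allometryTable <- function(includeUnderstory = TRUE) {
  tab <- .ALLOMETRY
  if (!includeUnderstory) tab <- tab[tab$group != "understory", ]
  rownames(tab) <- NULL
  tab
}

.lookupAllometry <- function(species, params) {
  idx <- match(species, params$species)
  if (anyNA(idx)) {
    bad <- unique(species[is.na(idx)])
    near <- unlist(lapply(bad, function(s)
      agrep(s, params$species, max.distance = 0.3, value = TRUE)))
    stop("unknown species: ", paste(bad, collapse = ", "),
         if (length(near)) paste0("; nearest known names: ",
                                  paste(unique(near), collapse = ", "))
         else "", call. = FALSE)
  }
  idx
}

#' Individual-tree aboveground biomass from DBH
#'
#' Evaluates the species-specific power law W = a * D^b.
#'
#' @param species character vector of species names (keys of
#'   [allometryTable()]).
#' @param dbh numeric vector of DBH (cm), recycled against `species`.
#' @param params coefficient table; defaults to the packaged one.
#' @param allowSmall logical; if `FALSE` (default) a DBH below the 5 cm
#'   census threshold is an error (zero DBH is permitted and yields 0 kg).
#' @return numeric vector of AGB in kg.
#' @examples
#' treeAgb("Betula platyphylla", 20)
#' @export
treeAgb <- function(species, dbh, params = allometryTable(),
                    allowSmall = FALSE) {
  if (any(dbh < 0)) stop("DBH must be >= 0")
  if (!allowSmall && any(dbh > 0 & dbh < 5))
    stop("DBH below the 5 cm census threshold; set allowSmall = TRUE ",
         "to evaluate anyway")
  n <- max(length(species), length(dbh))
  species <- rep_len(species, n)
  dbh <- rep_len(dbh, n)
  idx <- .lookupAllometry(species, params)
  params$a[idx] * dbh^params$b[idx]
}

#' Plot-level AGB density
#'
#' Sums individual-tree AGB over a plot tree list and converts to a
#' per-area density: AGB (Mg/ha) = (sum W kg / 1000) / plot area (ha).
#'
#' @param trees data.frame with columns `species` and `dbh_cm` (and
#'   optionally `plot_id`; when present a row per plot is returned).
#' @param plotArea plot area in hectares; default 0.06 (20 m x 30 m).
#' @param params coefficient table.
#' @param allowSmall passed to [treeAgb()].
#' @return data.frame with columns `plot_id`, `w_total_kg`, `agb_mg_ha`,
#'   `plot_area_ha`. An empty tree list gives density 0.
#' @export
plotAgbDensity <- function(trees, plotArea = 0.06, params = allometryTable(),
                           allowSmall = FALSE) {
  if (plotArea <= 0) stop("plotArea must be > 0")
  if (is.null(trees$plot_id)) trees$plot_id <- "plot"
  ids <- unique(trees$plot_id)
  if (nrow(trees) == 0)
    return(data.frame(plot_id = character(), w_total_kg = numeric(),
                      agb_mg_ha = numeric(), plot_area_ha = numeric(),
                      stringsAsFactors = FALSE))
  w <- treeAgb(trees$species, trees$dbh_cm, params, allowSmall)
  tot <- vapply(ids, function(i) sum(w[trees$plot_id == i]), 0)
  data.frame(plot_id = as.character(ids), w_total_kg = unname(tot),
             agb_mg_ha = unname(tot) / 1000 / plotArea,
             plot_area_ha = plotArea, stringsAsFactors = FALSE)
}
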
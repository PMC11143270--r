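#' @import methods
NULL

#' Regular geographic grid specification
#'
#' A regular lon/lat (WGS84-style geographic) grid.  Cells are half-open
#' `[edge, edge + res)` intervals on both axes and are stored row-major from
#' the north-west corner, so row 1 is the northernmost band and column 1 the
#' westernmost.  Values are registered at cell centres.
#'
#' @slot lonMin,lonMax,latMin,latMax numeric, window edges in degrees.
#' @slot res numeric, cell size in degrees (same for both axes).
#' @slot nRows,nCols integer, grid dimensions.
#'
#' @seealso [gridSpec()], [cellCenters()], [cellAreaKm2()]
#' @export
setClass("GridSpec",
  representation(
    lonMin = "numeric", lonMax = "numeric",
    latMin = "numeric", latMax = "numeric",
    res = "numeric", nRows = "integer", nCols = "integer"
  )
)

setValidity("GridSpec", function(object) {
  msgs <- character()
  if (object@res <= 0) msgs <- c(msgs, "res must be > 0")
  if (object@lonMax <= object@lonMin) msgs <- c(msgs, "lonMax must exceed lonMin")
  if (object@latMax <= object@latMin) msgs <- c(msgs, "latMax must exceed latMin")
  nc <- round((object@lonMax - object@lonMin) / object@res)
  nr <- round((object@latMax - object@latMin) / object@res)
  if (object@nCols != nc) msgs <- c(msgs, "nCols inconsistent with extent/res")
  if (object@nRows != nr) msgs <- c(msgs, "nRows inconsistent with extent/res")
  if (length(msgs)) msgs else TRUE
})

#' Multi-layer environmental raster stack
#'
#' Holds the nine predictor layers (six climate: `mat`, `tseason`, `prec`,
#' `pseason`, `gsl`, `npp`; three soil: `silt`, `cf`, `ph`), an `elevation`
#' layer, a shared land mask, and per-scenario future versions of the six
#' climate layers.  Soil and elevation are scenario-invariant.
#'
#' @slot grid a [GridSpec-class].
#' @slot layers named list of numeric matrices (current climate + soil +
#'   elevation), all `nRows x nCols`.
#' @slot future named list (one element per scenario) of named lists of the
#'   six climate-layer matrices.
#' @slot mask logical matrix, `TRUE` for land (data) cells.
#' @export
setClass("EnvStack",
  representation(grid = "GridSpec", layers = "list",
                 future = "list", mask = "matrix")
)

setValidity("EnvStack", function(object) {
  dims <- c(object@grid@nRows, object@grid@nCols)
  need <- c(climateLayerNames(), soilLayerNames(), "elevation")
  if (!all(need %in% names(object@layers)))
    return(paste("missing layers:", paste(setdiff(need, names(object@layers)), collapse = ", ")))
  for (nm in names(object@layers))
    if (!identical(dim(object@layers[[nm]]), dims))
      return(paste("layer", nm, "has wrong dimensions"))
  if (!identical(dim(object@mask), dims)) return("mask has wrong dimensions")
  for (sc in names(object@future)) {
    fl <- object@future[[sc]]
    if (!all(climateLayerNames() %in% names(fl)))
      return(paste("scenario", sc, "missing climate layers"))
    for (nm in names(fl))
      if (!identical(dim(fl[[nm]]), dims))
        return(paste("future layer", sc, nm, "has wrong dimensions"))
  }
  TRUE
})

#' Country and ecoregion tessellations
#'
#' Countries and ecoregions are independent Voronoi tessellations of the grid
#' window, stored both as convex polygons (closed rings, lon/lat) and as
#' rasterised label matrices (cell centre -> nearest seed, which is exactly
#' Voronoi membership).  Each ecoregion carries one of the seven forest-biome
#' labels, assigned from the latitude band of its seed point.
#'
#' @slot grid a [GridSpec-class].
#' @slot countryPolys,ecoPolys named lists of two-column (lon, lat) closed
#'   ring matrices.
#' @slot countrySeeds,ecoSeeds two-column matrices of Voronoi seed points.
#' @slot countryRaster,ecoRaster integer matrices of region ids per cell.
#' @slot biomes named character vector, biome label per ecoregion id.
#' @export
setClass("RegionSet",
  representation(grid = "GridSpec",
                 countryPolys = "list", countrySeeds = "matrix",
                 ecoPolys = "list", ecoSeeds = "matrix",
                 biomes = "character",
                 countryRaster = "matrix", ecoRaster = "matrix")
)

setValidity("RegionSet", function(object) {
  if (length(object@countryPolys) < 1) return("need at least one country")
  if (length(object@ecoPolys) < 1) return("need at least one ecoregion")
  if (!identical(sort(names(object@biomes)), sort(names(object@ecoPolys))))
    return("biomes must label every ecoregion exactly once")
  for (p in c(object@countryPolys, object@ecoPolys)) {
    if (!is.matrix(p) || ncol(p) != 2) return("polygons must be 2-column matrices")
    if (nrow(p) < 4) return("polygon ring too short")
    if (ringSelfIntersects(p)) return("self-intersecting polygon ring")
  }
  TRUE
})

#' Synthetic world: ground truth plus observed data
#'
#' Bundle of everything one run of the generator produces: the environmental
#' stack, the region tessellations, a tree-cover raster, per-species truth
#' (native countries, Gaussian niche parameters, realised occupancy), the
#' presence-only occurrence table, the presence-absence plot table, and a
#' Yule phylogeny over the species.
#'
#' @slot env an [EnvStack-class].
#' @slot regions a [RegionSet-class].
#' @slot treeCover numeric matrix, percent tree cover per cell.
#' @slot species data.frame of per-species truth (`species_id`,
#'   `max_prevalence`, `native_country_ids` as comma-joined string).
#' @slot niches named list: per species, list with `mean` and `sd` named
#'   numeric vectors over the niche predictors.
#' @slot occupancy named list of logical matrices: realised presence per cell.
#' @slot suitability named list of numeric matrices: true suitability per cell.
#' @slot occurrences data.frame (`species_id`, `lon`, `lat`, `source_db`).
#' @slot plots data.frame (`plot_id`, `lon`, `lat`, `species_id`, `present`).
#' @slot phylo an [ape::phylo] tree over the species ids.
#' @slot seed integer, the top-level seed.
#' @slot params list, the generator configuration used.
#' @export
setClass("SyntheticWorld",
  representation(env = "EnvStack", regions = "RegionSet",
                 treeCover = "matrix", species = "data.frame",
                 niches = "list", occupancy = "list", suitability = "list",
                 occurrences = "data.frame", plots = "data.frame",
                 phylo = "ANY", seed = "integer", params = "list")
)

#' Species geographic range
#'
#' The dispersal/biogeography constraint for one species: the intersection of
#' the buffered native-country union with the ecoregion support polygon,
#' realised as a cell mask on the predictor grid, with the constituent
#' geometry predicates retained.
#'
#' @slot speciesId character.
#' @slot grid a [GridSpec-class].
#' @slot cells logical matrix, `TRUE` where the cell centre is inside the
#'   range geometry.
#' @slot geometry list of geometry predicate components (see
#'   [bufferedNativeRange()] and [ecoregionSupportGeometry()]).
#' @slot provenance list: `n_obs_used`, `ecoregions_included`, `aggregated`.
#' @export
setClass("SpeciesRange",
  representation(speciesId = "character", grid = "GridSpec",
                 cells = "matrix", geometry = "list", provenance = "list")
)

setValidity("SpeciesRange", function(object) {
  if (!is.logical(object@cells)) return("cells must be a logical matrix")
  if (!identical(dim(object@cells), c(object@grid@nRows, object@grid@nCols)))
    return("cells has wrong dimensions")
  need <- c("n_obs_used", "ecoregions_included", "aggregated")
  if (!all(need %in% names(object@provenance)))
    return("provenance must carry n_obs_used, ecoregions_included, aggregated")
  TRUE
})

#' Fitted four-member SDM ensemble
#'
#' Two random forests and two gradient-boosted tree classifiers of different
#' complexity, fitted on identical training data; the ensemble probability is
#' the unweighted mean of the four member probabilities.  Carries the max-TSS
#' binarisation threshold found by cross-validation and the pooled
#' out-of-fold metrics.
#'
#' @slot speciesId character.
#' @slot members list of four fitted models (`rf_simple`, `rf_complex`,
#'   `gbt_simple`, `gbt_complex`).
#' @slot predictors character, names of the predictors used.
#' @slot threshold numeric in (0, 1).
#' @slot cvMetrics list with `TSS` and `AUC` (pooled out-of-fold).
#' @slot schedule list with `n_obs_training` and `n_PA_training`.
#' @export
setClass("EnsembleSDM",
  representation(speciesId = "character", members = "list",
                 predictors = "character", threshold = "numeric",
                 cvMetrics = "list", schedule = "list")
)

setValidity("EnsembleSDM", function(object) {
  need <- c("rf_simple", "rf_complex", "gbt_simple", "gbt_complex")
  if (!all(need %in% names(object@members))) return("ensemble needs its four members")
  if (length(object@threshold) != 1 || object@threshold <= 0 || object@threshold > 1)
    return("threshold must be a single value in (0, 1]")
  TRUE
})

#' Sites-by-species community matrix on an equal-area grid
#'
#' @slot sites data.frame with `site_id`, `lon`, `lat` (coarse cell centres).
#' @slot incidence 0/1 matrix, sites x species; column order fixed to the
#'   species list.
#' @export
setClass("CommunityMatrix",
  representation(sites = "data.frame", incidence = "matrix")
)

setValidity("CommunityMatrix", function(object) {
  if (nrow(object@sites) != nrow(object@incidence))
    return("sites and incidence row counts differ")
  if (is.null(colnames(object@incidence))) return("incidence needs species column names")
  if (any(rowSums(object@incidence) == 0)) return("all-zero site rows must be dropped")
  if (!all(object@incidence %in% c(0, 1))) return("incidence must be 0/1")
  TRUE
})
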
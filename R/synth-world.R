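#' Default synthetic-world configuration
#'
#' The default world is a 0.5-degree grid over a 60 x 120 degree window
#' (latitudes 0-60 N, so all four biome latitude bands are present), with 10
#' countries, 21 ecoregions, 25 species, one warming scenario (+3 degC on
#' mean annual temperature, x0.8 on precipitation), and 20% of land cells
#' deforested.  Any element can be overridden via `...`.
#'
#' @param ... overrides for the default elements.
#' @return a named list of generator parameters.
#' @examples
#' cfg <- worldConfig(nSpecies = 5, grid = list(-20, 20, 0, 40, 0.5))
#' @export
worldConfig <- function(...) {
  cfg <- list(
    grid = list(lonMin = -60, lonMax = 60, latMin = 0, latMax = 60, res = 0.5),
    nCountries = 10,
    nEcoregions = 21,
    nSpecies = 25,
    obsIntensity = 2,
    nPlots = 300,
    oceanFrac = 0.1,
    scenarios = list(ssp585 = list(dT = 3, dP = 0.8)),
    baseCover = 0.6,
    deforestationFrac = 0.2
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Generate a complete synthetic world
#'
#' Runs every generator off one top-level seed through named substreams
#' (`env`, `regions`, `phylo`, `occ`, `cover`), so a fixed seed gives
#' bit-identical worlds and the stages cannot cross-contaminate each other's
#' randomness.
#'
#' @param seed integer top-level seed.
#' @param config a [worldConfig()] list.
#' @return a [SyntheticWorld-class].
#' @examples
#' \donttest{
#' w <- makeWorld(seed = 1, config = worldConfig(
#'   grid = list(-20, 20, 0, 40, 1), nSpecies = 5, nCountries = 4,
#'   nEcoregions = 8, nPlots = 80))
#' w
#' }
#' @export
makeWorld <- function(seed, config = worldConfig()) {
  seed <- as.integer(seed)
  grid <- do.call(gridSpec, unname(config$grid))
  env <- generateEnvStack(grid, seed, scenarios = config$scenarios,
                          oceanFrac = config$oceanFrac)
  regions <- generateRegions(grid, config$nCountries, config$nEcoregions, seed)
  sp <- generateSpeciesOccurrences(env, regions, config$nSpecies,
                                   obsIntensity = config$obsIntensity,
                                   seed = seed, nPlots = config$nPlots)
  cover <- generateTreeCover(grid, config$baseCover, config$deforestationFrac,
                             seed, mask = env@mask)
  phy <- generatePhylogeny(sp$species$species_id, seed)
  new("SyntheticWorld", env = env, regions = regions, treeCover = cover,
      species = sp$species, niches = sp$niches,
      occupancy = sp$occupancy, suitability = sp$suitability,
      occurrences = sp$occurrences, plots = sp$plots,
      phylo = phy, seed = seed, params = config)
}

#' Accessors for synthetic worlds
#'
#' @param world a [SyntheticWorld-class].
#' @param speciesId species id.
#' @return components as named.
#' @export
worldSpecies <- function(world) world@species$species_id

#' @rdname worldSpecies
#' @export
worldOccurrences <- function(world) world@occurrences

#' @rdname worldSpecies
#' @export
worldPlots <- function(world) world@plots

#' @rdname worldSpecies
#' @export
worldPhylo <- function(world) world@phylo

#' @rdname worldSpecies
#' @export
worldEnv <- function(world) world@env

#' @rdname worldSpecies
#' @export
worldRegions <- function(world) world@regions

#' @rdname worldSpecies
#' @export
worldTreeCover <- function(world) world@treeCover

#' @rdname worldSpecies
#' @export
nativeCountries <- function(world, speciesId) {
  row <- world@species[world@species$species_id == speciesId, ]
  if (nrow(row) == 0) stop("unknown species: ", speciesId)
  strsplit(row$native_country_ids, ",")[[1]]
}

#' @rdname worldSpecies
#' @export
trueSuitabilityMap <- function(world, speciesId) world@suitability[[speciesId]]

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf(paste0("SyntheticWorld (seed %d): %d species, %d occurrence records, ",
                     "%d plots\n  "),
              object@seed, nrow(object@species), nrow(object@occurrences),
              length(unique(object@plots$plot_id))))
  show(object@env)
  cat("  "); show(object@regions)
})
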
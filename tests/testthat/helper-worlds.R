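# Shared fixtures, built once per test run.  Small worlds keep the suite
# fast; everything is generated in code from fixed seeds.

tinyWorldConfig <- function(...) {
  worldConfig(grid = list(-20, 20, 0, 40, 1), nSpecies = 6, nCountries = 5,
              nEcoregions = 8, nPlots = 80, ...)
}

.fixtures <- new.env(parent = emptyenv())

fixtureWorld <- function() {
  if (is.null(.fixtures$tiny)) .fixtures$tiny <- makeWorld(seed = 42, tinyWorldConfig())
  .fixtures$tiny
}

# Aggregated occurrences of the fixture world.
fixtureAgg <- function() {
  if (is.null(.fixtures$agg)) {
    w <- fixtureWorld()
    occ <- mergeOccurrences(list(worldOccurrences(w)), w@species$species_id)
    .fixtures$agg <- aggregateToGrid(occ, envGrid(worldEnv(w)), envMask(worldEnv(w)))
  }
  .fixtures$agg
}

# One fitted species (range + training + model + maps), shared across tests.
fixtureFit <- function() {
  if (is.null(.fixtures$fit)) {
    w <- fixtureWorld()
    agg <- fixtureAgg()
    n <- speciesCellCounts(agg)
    sp <- names(n)[which(n >= 50)[1]]
    cells <- agg[agg$species_id == sp, c("row", "col")]
    rg <- buildGeographicRange(worldRegions(w), nativeCountries(w, sp), cells,
                               speciesId = sp)
    sched <- pseudoabsenceSchedule(nrow(cells))
    tr <- suppressWarnings(sampleTraining(cells, rg, worldEnv(w), sched, seed = 9))
    model <- fitEnsemble(tr, nrow(cells), seed = 9, speciesId = sp)
    maps <- predictAndBinarize(model, worldEnv(w), rg, "current")
    .fixtures$fit <- list(world = w, species = sp, cells = cells, range = rg,
                          training = tr, model = model, maps = maps)
  }
  .fixtures$fit
}

# A rectangle ring (closed, counter-clockwise).
rectRing <- function(lon0, lon1, lat0, lat1) {
  rbind(c(lon0, lat0), c(lon1, lat0), c(lon1, lat1), c(lon0, lat1), c(lon0, lat0))
}

# Great-circle distance in km used as an independent oracle in tests.
oracleDistKm <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = 6371008.8) / 1000
}
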
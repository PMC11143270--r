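#' Default pipeline configuration
#'
#' One config drives all stages; each stage reads only its own block.  The
#' defaults reproduce the package's reference desk-scale study: the default
#' synthetic world, modelling floor of 20 distinct cells, analysis floor of
#' 90, the strongest-warming scenario for the climate comparison, and a
#' 400 km community grid (the ordinations need only a few hundred sites).
#'
#' @param seed integer top-level seed.
#' @param ... overrides for any config element.
#' @return nested config list.
#' @export
pipelineConfig <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    world = worldConfig(),
    prep = list(minObsModel = 20, minObsAnalysis = 90),
    range = list(bufferKm = 1000, radiusKm = 1000, minNeighbors = 3,
                 nearKm = 200, smallBboxKm = 1000, maxCells = 10000,
                 coarseFactor = 10),
    sdm = list(hyper = ensembleHyper(), kFolds = 3, minPlotPresences = 5),
    ordination = list(coarseCellKm = 400, kRange = 2:6, nmdsStarts = 20),
    occupancy = list(minCover = 10, minFraction = 0.2),
    climate = list(scenario = "ssp585"),
    writeArtifacts = TRUE
  )
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (nm == "world") {
      # world elements (e.g. the grid window) are replaced wholesale
      do.call(worldConfig, over[[nm]])
    } else if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      utils::modifyList(cfg[[nm]], over[[nm]])
    } else over[[nm]]
  }
  cfg
}

# Stage cache keyed by the config blocks the stage depends on.
stageCached <- function(outDir, stage, key, fun) {
  cacheDir <- file.path(outDir, "cache")
  dir.create(cacheDir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(cacheDir, paste0(stage, "-", rlang::hash(key), ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- fun()
  saveRDS(val, path)
  val
}

#' Run the full pipeline
#'
#' Executes synth -> prep -> range -> sdm -> ordinate -> occupancy ->
#' climate.  Each stage is cached under `outDir/cache` keyed by a hash of
#' its config block and its upstream keys, so re-running with an unchanged
#' config resumes from cache and deleting one stage's cache re-runs only
#' that stage onward.  A JSON manifest listing stage keys and the md5
#' checksums of all written artifacts is placed at `outDir/manifest.json`.
#'
#' @param config a [pipelineConfig()] list.
#' @param outDir output directory.
#' @param verbose print stage progress.
#' @return (invisibly) list with all stage results and the manifest.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("treeatlas"),
                        verbose = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed
  artifacts <- character(0)
  put <- function(name, writer) {
    p <- file.path(outDir, name)
    writer(p)
    artifacts[[name]] <<- p
    p
  }

  say("[synth] generating world (seed %d)", seed)
  keyWorld <- list("synth", seed, config$world)
  world <- stageCached(outDir, "synth", keyWorld, function() makeWorld(seed, config$world))
  if (isTRUE(config$writeArtifacts)) {
    writeWorld(world, file.path(outDir, "world"))
    artifacts[["world/manifest.yaml"]] <- file.path(outDir, "world", "manifest.yaml")
  }
  env <- world@env; regions <- world@regions; grid <- env@grid

  say("[prep] aggregating occurrences")
  keyPrep <- list("prep", keyWorld, config$prep)
  prep <- stageCached(outDir, "prep", keyPrep, function() {
    occ <- mergeOccurrences(list(world@occurrences), world@species$species_id)
    agg <- aggregateToGrid(occ, grid, env@mask)
    list(agg = agg,
         eligible = filterEligible(agg, config$prep$minObsModel),
         analysisSet = filterEligible(agg, config$prep$minObsAnalysis),
         counts = speciesCellCounts(agg))
  })
  put("species_counts.csv", function(p)
    utils::write.csv(data.frame(species_id = names(prep$counts),
                                n_obs = prep$counts,
                                eligible = names(prep$counts) %in% prep$eligible,
                                analysis = names(prep$counts) %in% prep$analysisSet,
                                row.names = NULL), p, row.names = FALSE))
  say("[prep] %d species eligible (>= %d cells), %d in analysis set (>= %d)",
      length(prep$eligible), config$prep$minObsModel,
      length(prep$analysisSet), config$prep$minObsAnalysis)

  say("[range] building geographic ranges")
  keyRange <- list("range", keyPrep, config$range)
  ranges <- stageCached(outDir, "range", keyRange, function() {
    out <- lapply(prep$eligible, function(sp) {
      cells <- prep$agg[prep$agg$species_id == sp, c("row", "col")]
      do.call(buildGeographicRange,
              c(list(regions = regions, nativeIds = nativeCountries(world, sp),
                     cells = cells, speciesId = sp), config$range))
    })
    stats::setNames(out, prep$eligible)
  })
  put("ranges.geojson", function(p) writeRangesGeoJSON(ranges, p))

  say("[sdm] fitting ensembles for %d species", length(prep$eligible))
  scenario <- config$climate$scenario
  keySdm <- list("sdm", keyRange, config$sdm, scenario)
  sdm <- stageCached(outDir, "sdm", keySdm, function() {
    res <- lapply(prep$eligible, function(sp) {
      cells <- prep$agg[prep$agg$species_id == sp, c("row", "col")]
      nObs <- nrow(cells)
      sched <- pseudoabsenceSchedule(nObs)
      training <- sampleTraining(cells, ranges[[sp]], env, sched,
                                 seed = substreamSeed(seed, paste0("train_", sp)))
      model <- fitEnsemble(training, nObs, hyper = config$sdm$hyper,
                           seed = substreamSeed(seed, paste0("sdm_", sp)),
                           speciesId = sp, kFolds = config$sdm$kFolds)
      mapsNow <- predictAndBinarize(model, env, ranges[[sp]], "current")
      mapsFut <- predictAndBinarize(model, env, ranges[[sp]], scenario)
      plotsSp <- world@plots[world@plots$species_id == sp, ]
      ev <- evaluatePlots(mapsNow$binary, plotsSp, ranges[[sp]],
                          config$sdm$minPlotPresences)
      truth <- world@occupancy[[sp]]
      truthBin <- ifelse(env@mask, as.numeric(truth), NA)
      list(model = model, now = mapsNow, fut = mapsFut, plotEval = ev,
           iou_truth = iouOverlap(mapsNow$binary, truthBin))
    })
    stats::setNames(res, prep$eligible)
  })
  metrics <- do.call(rbind, lapply(names(sdm), function(sp) {
    s <- sdm[[sp]]
    data.frame(species_id = sp, n_obs = prep$counts[[sp]],
               n_predictors = length(s$model@predictors),
               threshold = s$model@threshold,
               cv_tss = s$model@cvMetrics$TSS, cv_auc = s$model@cvMetrics$AUC,
               plot_tss = if (is.null(s$plotEval)) NA else s$plotEval$TSS,
               iou_truth = as.numeric(s$iou_truth))
  }))
  put("sdm_metrics.csv", function(p) utils::write.csv(metrics, p, row.names = FALSE))

  analysisSpecies <- intersect(prep$analysisSet, names(sdm))
  binNow <- lapply(sdm[analysisSpecies], function(s) s$now$binary)
  binFut <- lapply(sdm[analysisSpecies], function(s) s$fut$binary)

  say("[ordinate] community matrix and ordinations (%d species)", length(analysisSpecies))
  keyOrd <- list("ordinate", keySdm, config$ordination)
  ord <- stageCached(outDir, "ordinate", keyOrd, function() {
    cm <- buildCommunityMatrix(binNow, env, config$ordination$coarseCellKm)
    d <- sorensenDistances(cm)
    nmds <- runNMDS(d, nAxes = 3, seed = substreamSeed(seed, "nmds"),
                    nStarts = config$ordination$nmdsStarts)
    evo <- evoPCAHellinger(cm, world@phylo, nAxes = 3)
    envSites <- siteEnvironment(cm, env)
    keepTax <- iqrOutlierFilter(nmds$scores)
    keepPhy <- iqrOutlierFilter(evo$scores)
    list(cm = cm, nmds = nmds, evo = evo,
         rgbTax = rgbMap(nmds$scores), rgbPhy = rgbMap(evo$scores),
         clustTax = clusterBySilhouette(nmds$scores[keepTax, , drop = FALSE],
                                        config$ordination$kRange,
                                        seed = substreamSeed(seed, "ktax")),
         clustPhy = clusterBySilhouette(evo$scores[keepPhy, , drop = FALSE],
                                        config$ordination$kRange,
                                        seed = substreamSeed(seed, "kphy")),
         rdaTax = rdaVarpart(nmds$scores, envSites),
         rdaPhy = rdaVarpart(evo$scores, envSites),
         envPca = envPCA(envSites))
  })
  put("ordination_scores.csv", function(p) {
    rgbT <- ord$rgbTax; colnames(rgbT) <- paste0("tax_", colnames(rgbT))
    rgbP <- ord$rgbPhy; colnames(rgbP) <- paste0("phy_", colnames(rgbP))
    df <- cbind(ord$cm@sites[, c("site_id", "lon", "lat")],
                ord$nmds$scores, ord$evo$scores, rgbT, rgbP)
    utils::write.csv(df, p, row.names = FALSE)
  })

  say("[occupancy] range sizes and forest restriction")
  keyOcc <- list("occupancy", keySdm, config$occupancy)
  occ <- stageCached(outDir, "occupancy", keyOcc, function() {
    rec <- rangeRecords(binNow, world@treeCover, regions,
                        config$occupancy$minCover, config$occupancy$minFraction)
    nonEmpty <- !rec$empty_range
    forestBin <- lapply(binNow, constrainToForest, treeCover = world@treeCover,
                        minCover = config$occupancy$minCover)
    # per-biome reduction summary: species enter every biome they are
    # assigned to; paired test per biome where at least two species allow it
    biomeRows <- lapply(forestBiomes(), function(b) {
      inB <- nonEmpty & vapply(strsplit(rec$biomes, ","), function(x)
        b %in% x, logical(1))
      if (sum(inB) == 0) return(NULL)
      red <- rec$relative_reduction[inB]
      tb <- if (sum(inB) >= 2)
        reductionTest(rec$range_km2[inB], rec$forest_range_km2[inB])
      else NULL
      data.frame(biome = b, n_species = sum(inB),
                 median_reduction = stats::median(red),
                 q1 = quantile7(red, 0.25), q3 = quantile7(red, 0.75),
                 t = if (is.null(tb)) NA_real_ else tb$t,
                 p = if (is.null(tb)) NA_real_ else tb$p)
    })
    list(records = rec,
         medianMap = medianRangeMap(forestBin, rec, grid),
         test = if (sum(nonEmpty) >= 2)
           reductionTest(rec$range_km2[nonEmpty], rec$forest_range_km2[nonEmpty])
         else NULL,
         biomeReduction = do.call(rbind, biomeRows))
  })
  put("range_records.csv", function(p) utils::write.csv(occ$records, p, row.names = FALSE))
  put("occupancy_biome_summary.csv", function(p)
    utils::write.csv(occ$biomeReduction, p, row.names = FALSE))
  put("median_range_map.asc", function(p) writeAsciiGrid(occ$medianMap, grid, p))

  say("[climate] ecoregion responses under scenario %s", scenario)
  keyClim <- list("climate", keySdm, config$climate)
  clim <- stageCached(outDir, "climate", keyClim, function() {
    resp <- ecoregionResponses(binNow, binFut, regions, env@layers$elevation,
                               world@phylo, seed = substreamSeed(seed, "climate"))
    ok <- resp[!resp$empty_now & stats::complete.cases(
      resp[, c("frac_lost", "frac_gained", "median_abs_lat_shift",
               "median_elev_shift", "d_tax", "d_phy")]), ]
    counts <- table(ok$biome)
    pil <- if (sum(counts >= 2) >= 2)
      tryCatch(pillaiTest(ok[ok$biome %in% names(counts)[counts >= 2], ]),
               error = function(e) NULL)
    else NULL
    list(responses = resp, summary = biomeSummary(resp), pillai = pil)
  })
  put("ecoregion_responses.csv", function(p)
    utils::write.csv(clim$responses, p, row.names = FALSE))
  put("biome_summary.csv", function(p)
    utils::write.csv(clim$summary, p, row.names = FALSE))

  manifest <- list(
    seed = seed,
    stages = list(synth = rlang::hash(keyWorld), prep = rlang::hash(keyPrep),
                  range = rlang::hash(keyRange), sdm = rlang::hash(keySdm),
                  ordinate = rlang::hash(keyOrd), occupancy = rlang::hash(keyOcc),
                  climate = rlang::hash(keyClim)),
    artifacts = lapply(stats::setNames(nm = names(artifacts)), function(nm)
      list(path = nm, md5 = unname(tools::md5sum(artifacts[[nm]]))))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(world = world, prep = prep, ranges = ranges, sdm = sdm,
                 metrics = metrics, ordination = ord, occupancy = occ,
                 climate = clim, manifest = manifest, outDir = outDir))
}
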
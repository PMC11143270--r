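# Gaussian response product over the niche predictors, peak value 1 at the
# niche mean.
nicheResponse <- function(env, niche, scenario = "current") {
  g <- 1
  for (nm in names(niche$mean)) {
    x <- envLayer(env, nm, scenario)
    g <- g * exp(-0.5 * ((x - niche$mean[[nm]]) / niche$sd[[nm]])^2)
  }
  g
}

# True suitability under a scenario: Gaussian response rescaled so its
# maximum over the species' native land cells (under the *current* climate)
# equals max_prevalence.  The current-climate scale factor is reused for
# future scenarios so suitability is comparable across scenarios.
trueSuitability <- function(env, regions, niche, nativeIds, maxPrevalence,
                            scenario = "current") {
  g <- nicheResponse(env, niche, scenario)
  gnow <- if (scenario == "current") g else nicheResponse(env, niche, "current")
  nativeMask <- matrix(names(regions@countryPolys)[regions@countryRaster] %in% nativeIds,
                       nrow = nrow(g))
  peak <- max(gnow[nativeMask & env@mask])
  if (!is.finite(peak) || peak <= 0) peak <- 1
  pmin(maxPrevalence * g / peak, 1)
}

#' Generate species truths, occurrences and survey plots
#'
#' Each species gets a set of native countries, an independent-Gaussian
#' niche over mean annual temperature and annual precipitation (means drawn
#' from the realised climate of a random native land cell so every niche is
#' attainable), and a maximum prevalence.  True suitability at a cell is the
#' product of the Gaussian responses, rescaled so its maximum over native
#' land cells equals the species' maximum prevalence.  Realised occupancy is
#' one Bernoulli(suitability) draw per native land cell.  Presence-only
#' occurrence records are emitted per occupied cell (a small Poisson number
#' of duplicates across source databases, jittered within the cell);
#' presence-absence plots record the same realised occupancy exhaustively at
#' a random subset of land cells.
#'
#' @param env an [EnvStack-class].
#' @param regions a [RegionSet-class] on the same grid.
#' @param nSpecies number of species (>= 1).
#' @param obsIntensity expected number of occurrence records per occupied
#'   cell (>= 1); values above 1 create cross-database duplicates.
#' @param seed integer seed (substream `"occ"`).
#' @param nPlots number of presence-absence survey plots.
#' @param nicheSdMat,nicheSdPrec ranges (min, max) for the per-species niche
#'   standard deviations on temperature (degC) and precipitation (mm).
#' @param prevalenceRange range of `max_prevalence`.
#' @return list with `species` (data.frame of truths), `niches`,
#'   `suitability` and `occupancy` (named lists of matrices),
#'   `occurrences` (species_id, lon, lat, source_db) and
#'   `plots` (plot_id, lon, lat, species_id, present).
#' @export
generateSpeciesOccurrences <- function(env, regions, nSpecies, obsIntensity = 2,
                                       seed = 1, nPlots = 300,
                                       nicheSdMat = c(2, 5),
                                       nicheSdPrec = c(150, 500),
                                       prevalenceRange = c(0.3, 0.9)) {
  if (nSpecies < 1) stop("nSpecies must be >= 1")
  if (!identical(env@grid, regions@grid)) stop("env and regions must share the grid")
  withSubstream(seed, "occ", {
    grid <- env@grid
    cn <- countryIds(regions)
    landIdx <- which(env@mask)
    sourceDbs <- c("gbif", "bien", "museum", "plotdb")

    speciesIds <- sprintf("sp%03d", seq_len(nSpecies))
    species <- data.frame(species_id = speciesIds,
                          max_prevalence = stats::runif(nSpecies, prevalenceRange[1], prevalenceRange[2]),
                          native_country_ids = character(nSpecies),
                          stringsAsFactors = FALSE)
    niches <- vector("list", nSpecies); names(niches) <- speciesIds
    suitability <- vector("list", nSpecies); names(suitability) <- speciesIds
    occupancy <- vector("list", nSpecies); names(occupancy) <- speciesIds
    occ <- vector("list", nSpecies)
    centersAll <- cellCenters(grid)

    for (i in seq_len(nSpecies)) {
      nNative <- sample.int(length(cn), 1)
      native <- sort(sample(cn, nNative))
      species$native_country_ids[i] <- paste(native, collapse = ",")
      nativeMask <- matrix(cn[regions@countryRaster] %in% native, nrow = grid@nRows) & env@mask
      anchor <- if (any(nativeMask)) sample(which(nativeMask), 1) else sample(landIdx, 1)
      niche <- list(
        mean = c(mat = env@layers$mat[anchor], prec = env@layers$prec[anchor]),
        sd = c(mat = stats::runif(1, nicheSdMat[1], nicheSdMat[2]),
               prec = stats::runif(1, nicheSdPrec[1], nicheSdPrec[2]))
      )
      niches[[i]] <- niche
      s <- trueSuitability(env, regions, niche, native, species$max_prevalence[i])
      suitability[[i]] <- s
      p <- matrix(FALSE, grid@nRows, grid@nCols)
      idx <- which(nativeMask)
      p[idx] <- stats::runif(length(idx)) < s[idx]
      occupancy[[i]] <- p

      occIdx <- which(p)
      if (length(occIdx)) {
        nrec <- if (obsIntensity > 1) 1L + stats::rpois(length(occIdx), obsIntensity - 1) else rep(1L, length(occIdx))
        cellRep <- rep(occIdx, nrec)
        rr <- (cellRep - 1) %% grid@nRows + 1
        cc <- (cellRep - 1) %/% grid@nRows + 1
        ctr <- cellCenters(grid, rr, cc)
        occ[[i]] <- data.frame(
          species_id = speciesIds[i],
          lon = ctr[, 1] + stats::runif(length(cellRep), -0.5, 0.5) * grid@res * 0.999,
          lat = ctr[, 2] + stats::runif(length(cellRep), -0.5, 0.5) * grid@res * 0.999,
          source_db = sample(sourceDbs, length(cellRep), replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    occurrences <- do.call(rbind, occ[!vapply(occ, is.null, logical(1))])
    if (is.null(occurrences))
      occurrences <- data.frame(species_id = character(), lon = numeric(),
                                lat = numeric(), source_db = character())
    rownames(occurrences) <- NULL

    plotCells <- sample(landIdx, min(nPlots, length(landIdx)))
    pr <- (plotCells - 1) %% grid@nRows + 1
    pc <- (plotCells - 1) %/% grid@nRows + 1
    pctr <- cellCenters(grid, pr, pc)
    plots <- do.call(rbind, lapply(seq_along(plotCells), function(k) {
      data.frame(plot_id = sprintf("plot%04d", k),
                 lon = unname(pctr[k, 1]), lat = unname(pctr[k, 2]),
                 species_id = speciesIds,
                 present = unname(vapply(speciesIds, function(sp)
                   occupancy[[sp]][plotCells[k]], logical(1))),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    rownames(plots) <- NULL

    list(species = species, niches = niches, suitability = suitability,
         occupancy = occupancy, occurrences = occurrences, plots = plots)
  })
}

#' Generate a synthetic percent-tree-cover raster
#'
#' Baseline cover is a smooth field around `100 * baseCover`, floored at 10%
#' so that deforestation is the only source of sub-10% cover; an exact
#' `round(deforestationFrac * n_land)` randomly chosen land cells are then
#' set below 10% (uniform on [0, 10)).
#'
#' @param grid a [GridSpec-class].
#' @param baseCover baseline cover fraction in [0, 1].
#' @param deforestationFrac fraction of land cells deforested, in [0, 1].
#' @param seed integer seed (substream `"cover"`).
#' @param mask optional logical land mask (default: all cells are land).
#' @return numeric matrix of percent cover in [0, 100].
#' @export
generateTreeCover <- function(grid, baseCover = 0.6, deforestationFrac = 0.2,
                              seed = 1, mask = NULL) {
  if (baseCover < 0 || baseCover > 1 || deforestationFrac < 0 || deforestationFrac > 1)
    stop("baseCover and deforestationFrac must lie in [0, 1]")
  if (is.null(mask)) mask <- matrix(TRUE, grid@nRows, grid@nCols)
  withSubstream(seed, "cover", {
    noise <- gaussianSmooth(matrix(stats::rnorm(grid@nRows * grid@nCols, sd = 12),
                                   grid@nRows, grid@nCols), 2)
    cover <- pmin(pmax(100 * baseCover + noise, 10), 100)
    land <- which(mask)
    nDef <- round(deforestationFrac * length(land))
    if (nDef > 0) {
      def <- sample(land, nDef)
      cover[def] <- stats::runif(nDef, 0, 10 - 1e-9)
    }
    cover
  })
}
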
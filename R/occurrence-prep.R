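#' Merge occurrence tables and remove exact duplicates
#'
#' Concatenates occurrence tables from multiple source databases, keeps only
#' species whose names appear in the accepted checklist, and collapses
#' records with identical (species, lon, lat) coordinates to a single record
#' regardless of source database.  Only *identical* coordinates collapse;
#' records any finite distance apart are kept.
#'
#' @param tables list of occurrence data.frames (`species_id`, `lon`, `lat`,
#'   `source_db`).
#' @param acceptedNames character vector of accepted species names.
#' @return one merged, deduplicated occurrence data.frame.
#' @export
mergeOccurrences <- function(tables, acceptedNames) {
  if (is.data.frame(tables)) tables <- list(tables)
  occ <- do.call(rbind, tables)
  if (length(acceptedNames) == 0) {
    warning("empty accepted-names list: all records dropped")
    return(occ[0, , drop = FALSE])
  }
  occ <- occ[occ$species_id %in% acceptedNames, , drop = FALSE]
  occ <- occ[!duplicated(occ[, c("species_id", "lon", "lat")]), , drop = FALSE]
  rownames(occ) <- NULL
  occ
}

#' Aggregate occurrences to the predictor grid
#'
#' Assigns each record to its grid cell (half-open cell convention), drops
#' records that fall off the grid or on masked (no-data, e.g. water) cells,
#' and collapses multiple records in the same cell to one occupied cell per
#' species.
#'
#' @param occ occurrence data.frame (`species_id`, `lon`, `lat`).
#' @param grid a [GridSpec-class].
#' @param mask optional logical matrix (`TRUE` = usable cell).
#' @return data.frame (`species_id`, `row`, `col`), one row per occupied
#'   cell, plus attribute `n_obs`: named count of distinct cells per species.
#' @export
aggregateToGrid <- function(occ, grid, mask = NULL) {
  idx <- cellIndex(grid, occ$lon, occ$lat)
  keep <- !is.na(idx$row)
  if (!is.null(mask)) keep[keep] <- mask[cbind(idx$row[keep], idx$col[keep])]
  agg <- data.frame(species_id = occ$species_id[keep],
                    row = idx$row[keep], col = idx$col[keep],
                    stringsAsFactors = FALSE)
  agg <- agg[!duplicated(agg), , drop = FALSE]
  agg <- agg[order(agg$species_id, agg$row, agg$col), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "n_obs") <- table(factor(agg$species_id, levels = unique(agg$species_id)))
  agg
}

#' Count occupied cells per species
#'
#' @param agg output of [aggregateToGrid()].
#' @return named integer vector of distinct occupied cells per species.
#' @export
speciesCellCounts <- function(agg) {
  tab <- table(agg$species_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Modelling-eligibility filter
#'
#' Species with at least `minObs` spatially distinct occupied cells after
#' grid aggregation, sorted by id.  The study design uses 20 as the
#' modelling floor and 90 for species entering downstream analyses.
#'
#' @param agg output of [aggregateToGrid()].
#' @param minObs minimum number of occupied cells (>= 1).
#' @return character vector of eligible species ids.
#' @export
filterEligible <- function(agg, minObs = 20) {
  if (minObs < 1) stop("minObs must be >= 1")
  n <- speciesCellCounts(agg)
  sort(names(n)[n >= minObs])
}
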
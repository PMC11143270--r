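#' Range area of a binary distribution
#'
#' Sum of exact spherical cell areas over suitable cells.
#'
#' @param binary 0/1/NA matrix.
#' @param grid the [GridSpec-class] it lives on.
#' @return area in km^2.
#' @export
rangeArea <- function(binary, grid) {
  stopifnot(identical(dim(binary), c(grid@nRows, grid@nCols)))
  suit <- !is.na(binary) & binary == 1
  sum(cellAreaKm2(grid)[suit])
}

#' Constrain a distribution to forested cells
#'
#' Suitable cells are retained iff tree cover is at least `minCover`
#' percent (>= convention, so exactly 10% counts as forest).
#'
#' @param binary 0/1/NA matrix.
#' @param treeCover percent-cover matrix on the same grid.
#' @param minCover minimum percent cover.
#' @return constrained 0/1/NA matrix.
#' @export
constrainToForest <- function(binary, treeCover, minCover = 10) {
  if (!identical(dim(binary), dim(treeCover)))
    stop("tree cover is on a different grid")
  out <- binary
  out[!is.na(out) & out == 1 & treeCover < minCover] <- 0
  out
}

#' Assign a species to biomes
#'
#' For each biome, the fraction of the species' suitable area falling in
#' that biome's ecoregions; the species is assigned every biome holding at
#' least `minFraction` of its distribution (0 to all 7 labels possible).
#'
#' @param binary 0/1/NA matrix.
#' @param regions a [RegionSet-class] on the same grid.
#' @param minFraction assignment threshold on the area fraction.
#' @return character vector of biome labels; `attr(, "fractions")` carries
#'   all biome fractions.  Empty distribution gives no labels with
#'   attribute `empty = TRUE`.
#' @export
assignBiomes <- function(binary, regions, minFraction = 0.2) {
  areas <- cellAreaKm2(regions@grid)
  suit <- !is.na(binary) & binary == 1
  total <- sum(areas[suit])
  if (total == 0)
    return(structure(character(0), fractions = NULL, empty = TRUE))
  biome <- ecoregionBiomes(regions)[regions@ecoRaster]
  frac <- vapply(forestBiomes(), function(b) {
    inB <- matrix(biome == b, nrow = regions@grid@nRows)
    sum(areas[suit & inB]) / total
  }, numeric(1))
  structure(names(frac)[frac >= minFraction], fractions = frac, empty = FALSE)
}

#' Per-species occupancy range records
#'
#' Full and forest-constrained range sizes, relative reduction and biome
#' labels for a set of species.
#'
#' @param binaries named list of 0/1/NA matrices.
#' @param treeCover percent-cover matrix.
#' @param regions a [RegionSet-class].
#' @param minCover forest threshold (percent).
#' @param minFraction biome-assignment threshold.
#' @return data.frame: `species_id`, `range_km2`, `forest_range_km2`,
#'   `relative_reduction` (0, flagged via `empty_range`, when the full
#'   range is empty), `biomes` (comma-joined), `empty_range`.
#' @export
rangeRecords <- function(binaries, treeCover, regions, minCover = 10,
                         minFraction = 0.2) {
  grid <- regions@grid
  rows <- lapply(names(binaries), function(sp) {
    b <- binaries[[sp]]
    fb <- constrainToForest(b, treeCover, minCover)
    full <- rangeArea(b, grid)
    forest <- rangeArea(fb, grid)
    biomes <- assignBiomes(fb, regions, minFraction)
    data.frame(species_id = sp, range_km2 = full, forest_range_km2 = forest,
               relative_reduction = if (full > 0) 1 - forest / full else 0,
               biomes = paste(biomes, collapse = ","),
               empty_range = full == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median range-size map
#'
#' Per cell, the median (even counts: midpoint of the central pair) of the
#' forest-constrained range sizes of the species suitable there; cells
#' where no species is suitable are no-data.
#'
#' @param binaries named list of 0/1/NA matrices (forest-constrained maps
#'   when `records` holds forest range sizes).
#' @param records output of [rangeRecords()].
#' @param grid the [GridSpec-class].
#' @param constrained use `forest_range_km2` (default) or `range_km2`.
#' @return numeric matrix (NA where no species suitable).
#' @export
medianRangeMap <- function(binaries, records, grid, constrained = TRUE) {
  sizes <- stats::setNames(
    if (constrained) records$forest_range_km2 else records$range_km2,
    records$species_id)
  stack <- vapply(names(binaries),
                  function(sp) as.numeric(!is.na(binaries[[sp]]) & binaries[[sp]] == 1),
                  numeric(grid@nRows * grid@nCols))
  out <- matrix(NA_real_, grid@nRows, grid@nCols)
  anySp <- rowSums(stack) > 0
  out[anySp] <- apply(stack[anySp, , drop = FALSE], 1, function(v)
    stats::median(sizes[names(binaries)[v == 1]]))
  out
}

#' Paired test of unrestricted vs forest-restricted range sizes
#'
#' Two-sided paired t-test on the per-species (full - forest) differences.
#' Species pairs with zero-variance differences make the statistic
#' undefined; that degenerate case is flagged instead of tested.
#'
#' @param fullSizes,forestSizes paired numeric vectors (n >= 2).
#' @return list with `t`, `p`, `df`, `mean_difference`; `p` is `NA` with
#'   `degenerate = TRUE` when the differences have zero variance (including
#'   the all-equal case, where `t = 0`).
#' @export
reductionTest <- function(fullSizes, forestSizes) {
  stopifnot(length(fullSizes) == length(forestSizes), length(fullSizes) >= 2)
  d <- fullSizes - forestSizes
  if (stats::sd(d) == 0) {
    return(list(t = if (all(d == 0)) 0 else NA_real_, p = NA_real_,
                df = length(d) - 1, mean_difference = mean(d),
                degenerate = TRUE))
  }
  tt <- stats::t.test(fullSizes, forestSizes, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_difference = unname(tt$estimate), degenerate = FALSE)
}
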
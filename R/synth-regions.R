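# The seven forest biomes and the latitude bands (absolute degrees) that
# assign them.  Bands: tropical <= 23.5, mediterranean (23.5, 40],
# temperate (40, 55], boreal > 55.  Tropical and temperate bands cycle
# through their flavours so all seven labels can occur.
BIOME_BANDS <- list(
  tropical = c(0, 23.5), mediterranean = c(23.5, 40),
  temperate = c(40, 55), boreal = c(55, 90)
)
BAND_BIOMES <- list(
  tropical = c("Tropical Moist Broadleaf Forests",
               "Tropical Dry Broadleaf Forests",
               "Tropical Coniferous Forests"),
  mediterranean = "Mediterranean Forests",
  temperate = c("Temperate Broadleaf Forests", "Temperate Conifer Forests"),
  boreal = "Boreal Forests"
)

#' @rdname generateRegions
#' @export
forestBiomes <- function() unname(unlist(BAND_BIOMES))

# Sutherland-Hodgman clip of a convex ring (open, counter-clockwise or any
# orientation) against the half-plane {p : dot(p - a, n) <= 0}.
clipHalfPlane <- function(poly, a, n) {
  if (nrow(poly) == 0) return(poly)
  side <- (poly[, 1] - a[1]) * n[1] + (poly[, 2] - a[2]) * n[2]
  out <- matrix(numeric(0), ncol = 2)
  np <- nrow(poly)
  for (i in seq_len(np)) {
    j <- if (i == np) 1L else i + 1L
    ini <- side[i] <= 1e-12; inj <- side[j] <= 1e-12
    if (ini) out <- rbind(out, poly[i, ])
    if (xor(ini, inj)) {
      t <- side[i] / (side[i] - side[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# Voronoi cell of seeds[k, ] within the rectangle, as a closed convex ring.
voronoiCell <- function(seeds, k, box) {
  poly <- rbind(c(box[1], box[3]), c(box[2], box[3]),
                c(box[2], box[4]), c(box[1], box[4]))
  s <- seeds[k, ]
  for (j in seq_len(nrow(seeds))) {
    if (j == k) next
    mid <- (s + seeds[j, ]) / 2
    n <- seeds[j, ] - s
    poly <- clipHalfPlane(poly, mid, n)
    if (nrow(poly) < 3) break
  }
  if (nrow(poly) < 3) return(NULL)
  rbind(poly, poly[1, , drop = FALSE])
}

#' Generate synthetic country and ecoregion tessellations
#'
#' Countries and ecoregions are two independent Voronoi tessellations of the
#' grid window (planar lon/lat metric), so the polygon set tiles the window
#' exactly and the rasterised membership (nearest seed per cell centre) is
#' consistent with the polygons by construction.  Country seeds are uniform;
#' ecoregion seeds are stratified across the latitude bands intersecting the
#' window (allocation proportional to band height, at least one per band
#' when `nEcoregions` allows), and each ecoregion receives the forest-biome
#' label of its seed's band, cycling through the band's flavours.
#'
#' @param grid a [GridSpec-class].
#' @param nCountries,nEcoregions number of regions (each >= 1, at most the
#'   cell count).
#' @param seed integer seed (substream `"regions"`).
#' @return a [RegionSet-class].
#' @export
generateRegions <- function(grid, nCountries, nEcoregions, seed) {
  ncell <- grid@nRows * grid@nCols
  if (nCountries < 1 || nEcoregions < 1)
    stop("nCountries and nEcoregions must be >= 1")
  if (nCountries > ncell || nEcoregions > ncell)
    stop("cannot place more regions than grid cells")
  withSubstream(seed, "regions", {
    box <- c(grid@lonMin, grid@lonMax, grid@latMin, grid@latMax)
    cseeds <- cbind(stats::runif(nCountries, box[1], box[2]),
                    stats::runif(nCountries, box[3], box[4]))

    bands <- Filter(function(b) b[2] > grid@latMin && b[1] < grid@latMax,
                    lapply(BIOME_BANDS, function(b) {
                      lo <- max(b[1], grid@latMin); hi <- min(b[2], grid@latMax)
                      c(lo, hi)
                    }))
    heights <- vapply(bands, function(b) b[2] - b[1], numeric(1))
    alloc <- if (nEcoregions >= length(bands)) {
      a <- pmax(1, floor(nEcoregions * heights / sum(heights)))
      while (sum(a) > nEcoregions) a[which.max(a)] <- a[which.max(a)] - 1
      while (sum(a) < nEcoregions) a[which.max(heights / a)] <- a[which.max(heights / a)] + 1
      a
    } else {
      a <- integer(length(bands))
      a[order(heights, decreasing = TRUE)[seq_len(nEcoregions)]] <- 1L
      a
    }
    eseeds <- NULL; biomes <- character(0)
    for (bi in seq_along(bands)) {
      if (alloc[bi] == 0) next
      b <- bands[[bi]]
      pts <- cbind(stats::runif(alloc[bi], box[1], box[2]),
                   stats::runif(alloc[bi], b[1], b[2]))
      eseeds <- rbind(eseeds, pts)
      flavours <- BAND_BIOMES[[names(bands)[bi]]]
      biomes <- c(biomes, flavours[((seq_len(alloc[bi]) - 1) %% length(flavours)) + 1])
    }

    countryPolys <- lapply(seq_len(nCountries), function(k) voronoiCell(cseeds, k, box))
    ecoPolys <- lapply(seq_len(nrow(eseeds)), function(k) voronoiCell(eseeds, k, box))
    keepC <- !vapply(countryPolys, is.null, logical(1))
    keepE <- !vapply(ecoPolys, is.null, logical(1))
    countryPolys <- countryPolys[keepC]; cseeds <- cseeds[keepC, , drop = FALSE]
    ecoPolys <- ecoPolys[keepE]; eseeds <- eseeds[keepE, , drop = FALSE]
    biomes <- biomes[keepE]
    names(countryPolys) <- sprintf("C%02d", seq_along(countryPolys))
    names(ecoPolys) <- sprintf("E%02d", seq_along(ecoPolys))
    names(biomes) <- names(ecoPolys)

    ctr <- cellCenters(grid)
    nearest <- function(seeds) {
      d2 <- outer(ctr[, 1], seeds[, 1], "-")^2 + outer(ctr[, 2], seeds[, 2], "-")^2
      matrix(max.col(-d2, ties.method = "first"), nrow = grid@nRows, byrow = TRUE)
    }
    new("RegionSet", grid = grid,
        countryPolys = countryPolys, countrySeeds = cseeds,
        ecoPolys = ecoPolys, ecoSeeds = eseeds, biomes = biomes,
        countryRaster = nearest(cseeds), ecoRaster = nearest(eseeds))
  })
}

#' Accessors for region sets
#'
#' @param regions a [RegionSet-class].
#' @param id region id (e.g. `"C01"`, `"E03"`).
#' @return polygons, ids, biome labels or label rasters as named.
#' @export
countryIds <- function(regions) names(regions@countryPolys)

#' @rdname countryIds
#' @export
ecoregionIds <- function(regions) names(regions@ecoPolys)

#' @rdname countryIds
#' @export
countryPolygon <- function(regions, id) {
  if (!id %in% names(regions@countryPolys)) stop("unknown country id: ", id)
  regions@countryPolys[[id]]
}

#' @rdname countryIds
#' @export
ecoregionPolygon <- function(regions, id) {
  if (!id %in% names(regions@ecoPolys)) stop("unknown ecoregion id: ", id)
  regions@ecoPolys[[id]]
}

#' @rdname countryIds
#' @export
ecoregionBiomes <- function(regions) regions@biomes

#' @rdname countryIds
#' @export
countryRaster <- function(regions) regions@countryRaster

#' @rdname countryIds
#' @export
ecoregionRaster <- function(regions) regions@ecoRaster

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet: %d countries, %d ecoregions (%d biomes) on %d x %d grid\n",
              length(object@countryPolys), length(object@ecoPolys),
              length(unique(object@biomes)),
              object@grid@nRows, object@grid@nCols))
})
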
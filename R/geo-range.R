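#' Buffered native-country range geometry
#'
#' Union of the species' native-country polygons dilated by a great-circle
#' buffer (default 1000 km), compensating for gaps in the native-country
#' checklist and leaving room for range shifts under future climates.
#'
#' @param regions a [RegionSet-class].
#' @param nativeIds character vector of native country ids (non-empty).
#' @param bufferKm buffer distance in km.
#' @return a geometry usable with [geomContains()].
#' @export
bufferedNativeRange <- function(regions, nativeIds, bufferKm = 1000) {
  if (length(nativeIds) == 0) stop("nativeIds must be non-empty")
  unknown <- setdiff(nativeIds, countryIds(regions))
  if (length(unknown))
    stop("unknown country id(s): ", paste(unknown, collapse = ", "))
  newGeometry(list(list(type = "polyBuffer",
                        polys = regions@countryPolys[nativeIds],
                        bufferKm = bufferKm)))
}

#' Spatially supported observations
#'
#' An occupied cell is supported if at least `minNeighbors` *other* occupied
#' cells of the same species lie within `radiusKm` great-circle distance
#' (cell centre to cell centre).  Unsupported, isolated cells are treated as
#' vagrancy/noise and do not anchor the range polygon.
#'
#' @param cells data.frame with `row`, `col` (one species' occupied cells).
#' @param grid a [GridSpec-class].
#' @param radiusKm neighbourhood radius in km.
#' @param minNeighbors minimum number of other occupied cells in the
#'   neighbourhood.
#' @return the supported subset of `cells`.
#' @export
supportedObservations <- function(cells, grid, radiusKm = 1000, minNeighbors = 3) {
  n <- nrow(cells)
  if (n == 0) return(cells)
  ctr <- cellCenters(grid, cells$row, cells$col)
  counts <- integer(n)
  chunk <- max(1L, floor(4e6 / n))
  for (start in seq(1, n, by = chunk)) {
    ii <- start:min(start + chunk - 1, n)
    d <- geosphere::distm(ctr[ii, , drop = FALSE], ctr,
                          fun = function(a, b) geosphere::distHaversine(a, b, r = EARTH_RADIUS_M)) / 1000
    counts[ii] <- rowSums(d <= radiusKm) - 1L  # exclude self
  }
  cells[counts >= minNeighbors, , drop = FALSE]
}

# Great-circle spans (km) of a ring's lon/lat envelope, width measured at
# the envelope's centroid latitude.
bboxSpansKm <- function(ring) {
  lonr <- range(ring[, 1]); latr <- range(ring[, 2])
  midLat <- mean(latr)
  width <- EARTH_RADIUS_KM * cos(midLat * pi / 180) * diff(lonr) * pi / 180
  length <- EARTH_RADIUS_KM * diff(latr) * pi / 180
  c(width = width, length = length)
}

#' Ecoregion support geometry
#'
#' For each ecoregion containing at least one supported observation cell:
#' small ecoregions (bounding box under `smallBboxKm` in width or length)
#' are included whole with a `bufferKm` buffer; for larger ecoregions only
#' the part within `nearKm` of a supported observation is included, again
#' with a `bufferKm` buffer (the part is realised as the ecoregion's grid
#' cells within `nearKm` of a supported cell centre).  Returns the union;
#' empty if no ecoregion contains a supported cell (the caller falls back
#' to the buffered native range).
#'
#' @param regions a [RegionSet-class].
#' @param supportedCells data.frame with `row`, `col`.
#' @param nearKm proximity distance defining the supported part of large
#'   ecoregions.
#' @param bufferKm buffer applied to each included component.
#' @param smallBboxKm bounding-box threshold below which an ecoregion is
#'   included whole.
#' @return a geometry; `attr(, "ecoregions")` lists the included ids.
#' @export
ecoregionSupportGeometry <- function(regions, supportedCells, nearKm = 200,
                                     bufferKm = 1000, smallBboxKm = 1000) {
  grid <- regions@grid
  if (nrow(supportedCells) == 0) {
    g <- newGeometry(list())
    attr(g, "ecoregions") <- character(0)
    return(g)
  }
  supCtr <- cellCenters(grid, supportedCells$row, supportedCells$col)
  ecoAt <- regions@ecoRaster[cbind(supportedCells$row, supportedCells$col)]
  ids <- ecoregionIds(regions)[sort(unique(ecoAt))]
  comps <- list()
  for (id in ids) {
    ring <- regions@ecoPolys[[id]]
    spans <- bboxSpansKm(ring)
    if (any(spans < smallBboxKm)) {
      comps[[length(comps) + 1]] <- list(type = "polyBuffer",
                                         polys = list(ring), bufferKm = bufferKm)
    } else {
      rc <- which(regions@ecoRaster == match(id, ecoregionIds(regions)), arr.ind = TRUE)
      ctr <- cellCenters(grid, rc[, 1], rc[, 2])
      nearSup <- withinKmOfPoints(ctr, supCtr, nearKm)
      if (any(nearSup))
        comps[[length(comps) + 1]] <- list(type = "pointBuffer",
                                           points = ctr[nearSup, , drop = FALSE],
                                           bufferKm = bufferKm)
    }
  }
  g <- newGeometry(comps)
  attr(g, "ecoregions") <- ids
  g
}

#' Build a species' geographic range
#'
#' Intersection of the buffered native-country union with the ecoregion
#' support geometry, realised as a cell mask on the predictor grid.  If the
#' species has more than `maxCells` occupied cells they are first snapped to
#' a `coarseFactor`-times coarser grid and deduplicated (provenance flag
#' `aggregated`); if no ecoregion contains a supported observation the range
#' falls back to the buffered native range alone.
#'
#' @param regions a [RegionSet-class].
#' @param nativeIds native country ids.
#' @param cells data.frame with `row`, `col`: the species' occupied cells.
#' @param speciesId species id for the result.
#' @param bufferKm,radiusKm,minNeighbors,nearKm,smallBboxKm see
#'   [bufferedNativeRange()], [supportedObservations()] and
#'   [ecoregionSupportGeometry()].
#' @param maxCells occupied-cell count above which spatial aggregation is
#'   applied before range construction.
#' @param coarseFactor coarsening factor for that aggregation.
#' @return a [SpeciesRange-class].
#' @export
buildGeographicRange <- function(regions, nativeIds, cells, speciesId = "sp",
                                 bufferKm = 1000, radiusKm = 1000,
                                 minNeighbors = 3, nearKm = 200,
                                 smallBboxKm = 1000, maxCells = 10000,
                                 coarseFactor = 10) {
  grid <- regions@grid
  nObs <- nrow(cells)
  aggregated <- FALSE
  workCells <- cells
  if (nObs > maxCells) {
    aggregated <- TRUE
    coarse <- gridSpec(grid@lonMin, grid@lonMax, grid@latMin, grid@latMax,
                       grid@res * coarseFactor)
    ctr <- cellCenters(grid, cells$row, cells$col)
    ci <- cellIndex(coarse, ctr[, 1], ctr[, 2])
    ci <- ci[!is.na(ci$row) & !duplicated(ci), , drop = FALSE]
    cctr <- cellCenters(coarse, ci$row, ci$col)
    fi <- cellIndex(grid, cctr[, 1], cctr[, 2])
    workCells <- fi[!is.na(fi$row), , drop = FALSE]
  }
  sup <- supportedObservations(workCells, grid, radiusKm, minNeighbors)
  native <- bufferedNativeRange(regions, nativeIds, bufferKm)
  support <- ecoregionSupportGeometry(regions, sup, nearKm, bufferKm, smallBboxKm)
  mask <- rasterizeGeometry(native, grid)
  if (length(support$components) > 0)
    mask <- mask & rasterizeGeometry(support, grid)
  new("SpeciesRange", speciesId = speciesId, grid = grid, cells = mask,
      geometry = list(native = native, support = support),
      provenance = list(n_obs_used = nObs,
                        ecoregions_included = attr(support, "ecoregions"),
                        aggregated = aggregated))
}

#' @rdname buildGeographicRange
#' @param range a [SpeciesRange-class].
#' @export
rangeCells <- function(range) range@cells

#' @rdname buildGeographicRange
#' @export
rangeProvenance <- function(range) range@provenance

setMethod("show", "SpeciesRange", function(object) {
  cat(sprintf("SpeciesRange %s: %d of %d cells in range (%d obs used%s)\n",
              object@speciesId, sum(object@cells), length(object@cells),
              object@provenance$n_obs_used,
              if (isTRUE(object@provenance$aggregated)) ", aggregated" else ""))
})

#' Write species ranges as GeoJSON
#'
#' One feature per species; the geometry is the rasterised range dissolved
#' to grid-resolution cell rectangles, with provenance in the properties.
#'
#' @param ranges list of [SpeciesRange-class] objects.
#' @param path output path.
#' @export
writeRangesGeoJSON <- function(ranges, path) {
  feats <- lapply(ranges, function(rg) {
    idx <- which(rg@cells, arr.ind = TRUE)
    g <- rg@grid
    coords <- lapply(seq_len(nrow(idx)), function(k) {
      lon0 <- g@lonMin + (idx[k, 2] - 1) * g@res
      lat1 <- g@latMin + (g@nRows - idx[k, 1] + 1) * g@res
      lat0 <- lat1 - g@res; lon1 <- lon0 + g@res
      list(list(c(lon0, lat0), c(lon1, lat0), c(lon1, lat1),
                c(lon0, lat1), c(lon0, lat0)))
    })
    list(type = "Feature",
         properties = list(species_id = rg@speciesId,
                           n_obs_used = rg@provenance$n_obs_used,
                           ecoregions_included = as.list(rg@provenance$ecoregions_included),
                           aggregated = rg@provenance$aggregated),
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = unname(feats)),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
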
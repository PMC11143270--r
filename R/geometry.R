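# Spherical geometry predicates.  Range geometries are represented as
# unions of two component kinds:
#   polyBuffer  — one or more lon/lat polygon rings dilated by a
#                 great-circle buffer (distance to the ring measured by
#                 exact cross-track distance on the sphere);
#   pointBuffer — a set of points (cell centres) dilated by a great-circle
#                 buffer.
# Downstream only ever needs membership tests of points in a geometry, so
# buffering is exact (no projection approximation) and intersection /
# union / fallback logic stays simple boolean algebra.

# Great-circle distance (km) from points to one segment a-b, vectorized
# over points: cross-track distance where the projection falls inside the
# segment, endpoint distance otherwise.
distToSegmentKm <- function(pts, a, b) {
  segLen <- geosphere::distHaversine(a, b, r = EARTH_RADIUS_M)
  dA <- geosphere::distHaversine(pts, a, r = EARTH_RADIUS_M)
  dB <- geosphere::distHaversine(pts, b, r = EARTH_RADIUS_M)
  if (segLen < 1) return(pmin(dA, dB) / 1000)
  # alongTrackDistance is unsigned, so test the projection from both ends:
  # it falls inside the segment iff both along-track distances fit
  alongA <- geosphere::alongTrackDistance(a, b, pts, r = EARTH_RADIUS_M)
  alongB <- geosphere::alongTrackDistance(b, a, pts, r = EARTH_RADIUS_M)
  xt <- abs(geosphere::dist2gc(a, b, pts, r = EARTH_RADIUS_M))
  d <- ifelse(alongA <= segLen & alongB <= segLen, xt, pmin(dA, dB))
  d / 1000
}

# Min great-circle distance (km) from each point to a closed ring.
distToRingKm <- function(pts, ring) {
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(ring) - 1)) {
    d <- pmin(d, distToSegmentKm(pts, ring[i, ], ring[i + 1, ]))
  }
  d
}

pointsInRing <- function(pts, ring) {
  mgcv::in.out(ring, pts)
}

newGeometry <- function(components) {
  structure(list(components = components), class = "geoGeometry")
}

#' Test points against a range geometry
#'
#' A point is contained if it falls in any component: inside a (buffered)
#' polygon, or within the buffer distance of a point set.
#'
#' @param geom a geometry as returned by [bufferedNativeRange()] or
#'   [ecoregionSupportGeometry()].
#' @param pts two-column (lon, lat) matrix.
#' @return logical vector.
#' @export
geomContains <- function(geom, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  out <- rep(FALSE, nrow(pts))
  for (comp in geom$components) {
    todo <- which(!out)
    if (!length(todo)) break
    sub <- pts[todo, , drop = FALSE]
    if (comp$type == "polyBuffer") {
      hit <- rep(FALSE, nrow(sub))
      for (ring in comp$polys) {
        miss <- which(!hit)
        if (!length(miss)) break
        inside <- pointsInRing(sub[miss, , drop = FALSE], ring)
        hit[miss] <- inside
        if (comp$bufferKm > 0) {
          miss2 <- miss[!inside]
          if (length(miss2)) {
            cand <- bboxCandidates(sub[miss2, , drop = FALSE], ring, comp$bufferKm)
            if (any(cand)) {
              dd <- distToRingKm(sub[miss2[cand], , drop = FALSE], ring)
              hit[miss2[cand]] <- dd <= comp$bufferKm
            }
          }
        }
      }
      out[todo] <- hit
    } else if (comp$type == "pointBuffer") {
      out[todo] <- withinKmOfPoints(sub, comp$points, comp$bufferKm)
    } else stop("unknown geometry component type: ", comp$type)
  }
  out
}

# Cheap bounding-box prescreen before exact ring distances.
bboxCandidates <- function(pts, ring, bufferKm) {
  dlat <- bufferKm / 111.2 * 1.02
  latr <- range(ring[, 2])
  maxAbsLat <- min(89, max(abs(latr)) + dlat)
  dlon <- bufferKm / (111.2 * max(0.05, cos(maxAbsLat * pi / 180))) * 1.02
  lonr <- range(ring[, 1])
  pts[, 1] >= lonr[1] - dlon & pts[, 1] <= lonr[2] + dlon &
    pts[, 2] >= latr[1] - dlat & pts[, 2] <= latr[2] + dlat
}

# Is each point within `km` of any of `ref` points?  Bounding-box prescreen
# plus chunked haversine.
withinKmOfPoints <- function(pts, ref, km) {
  out <- rep(FALSE, nrow(pts))
  if (nrow(ref) == 0) return(out)
  dlat <- km / 111.2 * 1.02
  coslat <- pmax(0.05, cos(pmin(89, abs(pts[, 2])) * pi / 180))
  dlon <- km / (111.2 * coslat) * 1.02
  cand <- which(pts[, 2] >= min(ref[, 2]) - dlat & pts[, 2] <= max(ref[, 2]) + dlat &
                pts[, 1] >= min(ref[, 1]) - dlon & pts[, 1] <= max(ref[, 1]) + dlon)
  if (length(cand) == 0) return(out)
  chunk <- max(1L, floor(4e6 / nrow(ref)))
  for (start in seq(1, length(cand), by = chunk)) {
    ii <- cand[start:min(start + chunk - 1, length(cand))]
    d <- geosphere::distm(pts[ii, , drop = FALSE], ref,
                          fun = function(a, b) geosphere::distHaversine(a, b, r = EARTH_RADIUS_M))
    out[ii] <- apply(d, 1, min) <= km * 1000
  }
  out
}

# Rasterise a geometry to a logical cell mask on a grid.
rasterizeGeometry <- function(geom, grid) {
  hits <- geomContains(geom, cellCenters(grid))
  matrix(hits, nrow = grid@nRows, byrow = TRUE)
}
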
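# Internal constants and small helpers shared across modules.

# Mean Earth radius (m); all great-circle math in the package uses the same
# spherical Earth so cell areas, buffers and distances are mutually
# consistent.
EARTH_RADIUS_M <- 6371008.8
EARTH_RADIUS_KM <- EARTH_RADIUS_M / 1000

#' Names of the climate, soil and all predictor layers
#'
#' Six climate predictors (mean annual temperature, temperature seasonality,
#' annual precipitation, precipitation seasonality, growing-season length,
#' net primary productivity) and three soil predictors (silt content, coarse
#' fragments, pH).  The fixed order also serves as the deterministic
#' tie-break for predictor selection.
#'
#' @return character vector of layer names.
#' @export
climateLayerNames <- function() c("mat", "tseason", "prec", "pseason", "gsl", "npp")

#' @rdname climateLayerNames
#' @export
soilLayerNames <- function() c("silt", "cf", "ph")

#' @rdname climateLayerNames
#' @export
predictorNames <- function() c(climateLayerNames(), soilLayerNames())

# Named random substreams: every generator derives its own seed from the
# top-level seed and a stream name, so adding draws to one stage never
# perturbs another.  Plain 32-bit arithmetic hash, kept below 2^31.
substreamSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- as.double(seed %% 2147483647)
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

withSubstream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substreamSeed(seed, name))
  expr
}

# Great-circle haversine distance in km between two lon/lat matrices.
gcDistKm <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M) / 1000
}

# Full pairwise great-circle distance matrix (km) for a set of lon/lat points.
gcDistMatrixKm <- function(pts) {
  geosphere::distm(pts, fun = function(a, b) geosphere::distHaversine(a, b, r = EARTH_RADIUS_M)) / 1000
}

# Quantile with the documented convention (linear interpolation between
# order statistics, stats type 7), used consistently for boxplots, the IQR
# outlier filter and biome summaries.
quantile7 <- function(x, probs) stats::quantile(x, probs, type = 7, names = FALSE, na.rm = TRUE)

# Separable gaussian smoothing of a matrix (reflected edges); used to give
# synthetic fields spatial autocorrelation.
gaussianSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad <- function(v) c(rev(v[seq_len(half)]), v, rev(v[(length(v) - half + 1):length(v)]))
  smooth1 <- function(v) stats::filter(pad(v), k, sides = 2)[(half + 1):(half + length(v))]
  m2 <- apply(m, 2, smooth1)
  t(apply(t(m2), 2, smooth1))
}

# Does a closed ring self-intersect?  O(n^2) segment test; rings here are
# tiny (Voronoi cells).
ringSelfIntersects <- function(ring) {
  n <- nrow(ring) - 1L  # last vertex repeats the first
  if (n < 3) return(TRUE)
  segInt <- function(p1, p2, p3, p4) {
    d1 <- crossZ(p3, p4, p1); d2 <- crossZ(p3, p4, p2)
    d3 <- crossZ(p1, p2, p3); d4 <- crossZ(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  crossZ <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next  # adjacent through the closure
      if (segInt(ring[i, ], ring[i + 1, ], ring[j, ], ring[j + 1, ])) return(TRUE)
    }
  }
  FALSE
}
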
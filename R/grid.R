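#' Construct a grid specification
#'
#' @param lonMin,lonMax,latMin,latMax window edges in degrees.
#' @param res cell size in degrees.
#' @return a [GridSpec-class].
#' @examples
#' g <- gridSpec(-60, 60, 0, 60, res = 0.5)
#' gridDims(g)
#' @export
gridSpec <- function(lonMin, lonMax, latMin, latMax, res) {
  nCols <- as.integer(round((lonMax - lonMin) / res))
  nRows <- as.integer(round((latMax - latMin) / res))
  if (nRows <= 1 || nCols <= 1)
    stop("degenerate grid: need more than one cell per axis")
  new("GridSpec", lonMin = lonMin, lonMax = lonMax, latMin = latMin,
      latMax = latMax, res = res, nRows = nRows, nCols = nCols)
}

#' @rdname gridSpec
#' @param grid a [GridSpec-class].
#' @export
gridDims <- function(grid) c(rows = grid@nRows, cols = grid@nCols)

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %g deg, lon [%g, %g], lat [%g, %g]\n",
              object@nRows, object@nCols, object@res,
              object@lonMin, object@lonMax, object@latMin, object@latMax))
})

#' Cell centre coordinates
#'
#' @param grid a [GridSpec-class].
#' @param rows,cols optional integer vectors of cell indices; by default all
#'   cells in row-major order (row 1 = northernmost).
#' @return two-column matrix (lon, lat) of cell centres.
#' @export
cellCenters <- function(grid, rows = NULL, cols = NULL) {
  if (is.null(rows)) {
    rows <- rep(seq_len(grid@nRows), each = grid@nCols)
    cols <- rep(seq_len(grid@nCols), times = grid@nRows)
  }
  cbind(lon = grid@lonMin + (cols - 0.5) * grid@res,
        lat = grid@latMin + (grid@nRows - rows + 0.5) * grid@res)
}

#' Assign points to grid cells
#'
#' Half-open cell convention: a point on a shared edge belongs to the cell
#' whose `[edge, edge + res)` interval contains it; points at the very top /
#' right window edge fall off-grid.
#'
#' @param grid a [GridSpec-class].
#' @param lon,lat point coordinates in degrees.
#' @return data.frame with `row`, `col` (NA where off-grid).
#' @export
cellIndex <- function(grid, lon, lat) {
  col <- floor((lon - grid@lonMin) / grid@res) + 1
  row <- grid@nRows - floor((lat - grid@latMin) / grid@res)
  off <- col < 1 | col > grid@nCols | row < 1 | row > grid@nRows
  col[off] <- NA_integer_; row[off] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Spherical cell areas
#'
#' Exact spherical areas `R^2 * dlambda * (sin(phi_N) - sin(phi_S))` per
#' latitude band, so all downstream area arithmetic is closed-form.
#'
#' @param grid a [GridSpec-class].
#' @return numeric matrix of cell areas in km^2.
#' @export
cellAreaKm2 <- function(grid) {
  i <- seq_len(grid@nRows)
  latN <- grid@latMin + (grid@nRows - i + 1) * grid@res
  latS <- grid@latMin + (grid@nRows - i) * grid@res
  band <- EARTH_RADIUS_KM^2 * (grid@res * pi / 180) *
    (sin(latN * pi / 180) - sin(latS * pi / 180))
  matrix(rep(band, grid@nCols), nrow = grid@nRows)
}
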
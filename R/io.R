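# Plain-text raster and vector writers.  Rasters use the ESRI ASCII grid
# format (.asc), which standard GIS tools (GDAL, QGIS) read directly; no
# GeoTIFF-capable package is declared, and .asc carries the same
# georeferencing (origin, cell size, nodata) in text form.

#' Write / read a raster layer as an ESRI ASCII grid
#'
#' @param m numeric matrix (row 1 = northernmost band, matching
#'   [GridSpec-class] layout).
#' @param grid a [GridSpec-class].
#' @param path output path (conventionally `.asc`).
#' @param nodata value written for `NA` cells.
#' @return `readAsciiGrid` returns a list with `grid` and `values`.
#' @export
writeAsciiGrid <- function(m, grid, path, nodata = -9999) {
  stopifnot(identical(dim(m), c(grid@nRows, grid@nCols)))
  hdr <- c(
    sprintf("ncols %d", grid@nCols),
    sprintf("nrows %d", grid@nRows),
    sprintf("xllcorner %.10g", grid@lonMin),
    sprintf("yllcorner %.10g", grid@latMin),
    sprintf("cellsize %.10g", grid@res),
    sprintf("NODATA_value %g", nodata)
  )
  m2 <- m
  m2[is.na(m2)] <- nodata
  rows <- apply(m2, 1, function(v) paste(format(v, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  kv <- stats::setNames(vapply(hdr, function(x) as.numeric(x[2]), numeric(1)),
                        tolower(vapply(hdr, `[`, character(1), 1)))
  nr <- as.integer(kv[["nrows"]]); nc <- as.integer(kv[["ncols"]])
  vals <- scan(text = paste(lines[-(1:6)], collapse = " "), quiet = TRUE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == kv[["nodata_value"]]] <- NA
  g <- gridSpec(kv[["xllcorner"]], kv[["xllcorner"]] + nc * kv[["cellsize"]],
                kv[["yllcorner"]], kv[["yllcorner"]] + nr * kv[["cellsize"]],
                kv[["cellsize"]])
  list(grid = g, values = m)
}

# GeoJSON FeatureCollection from polygons (closed lon/lat rings) and a
# data.frame of properties (one row per feature).
geojsonFeatureCollection <- function(polys, properties) {
  feats <- lapply(seq_along(polys), function(i) {
    ring <- polys[[i]]
    list(type = "Feature",
         properties = as.list(properties[i, , drop = FALSE]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(r) unname(ring[r, ])))))
  })
  list(type = "FeatureCollection", features = feats)
}

#' Write polygons as GeoJSON
#'
#' @param polys named list of closed lon/lat ring matrices.
#' @param properties data.frame of per-feature properties.
#' @param path output path.
#' @export
writeGeoJSON <- function(polys, properties, path) {
  jsonlite::write_json(geojsonFeatureCollection(polys, properties), path,
                       auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Write all artifacts of a synthetic world to a directory
#'
#' Emits one `.asc` per raster layer (current and future climate, elevation,
#' tree cover), GeoJSON for countries and ecoregions (with `id` and `biome`
#' properties), CSVs for occurrences and plots, Newick for the phylogeny,
#' and a YAML manifest listing every artifact with its md5 checksum and the
#' seed.
#'
#' @param world a [SyntheticWorld-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest as a list.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- world@env@grid
  paths <- character(0)
  putRaster <- function(m, name) {
    p <- file.path(dir, paste0(name, ".asc"))
    mm <- m; mm[!world@env@mask] <- NA
    writeAsciiGrid(mm, grid, p)
    paths[[name]] <<- p
  }
  for (nm in names(world@env@layers)) putRaster(world@env@layers[[nm]], nm)
  for (sc in names(world@env@future))
    for (nm in names(world@env@future[[sc]]))
      putRaster(world@env@future[[sc]][[nm]], paste0(nm, "_", sc))
  putRaster(world@treeCover, "tree_cover")

  p <- file.path(dir, "countries.geojson")
  writeGeoJSON(world@regions@countryPolys,
               data.frame(id = countryIds(world@regions)), p)
  paths[["countries"]] <- p
  p <- file.path(dir, "ecoregions.geojson")
  writeGeoJSON(world@regions@ecoPolys,
               data.frame(id = ecoregionIds(world@regions),
                          biome = unname(ecoregionBiomes(world@regions))), p)
  paths[["ecoregions"]] <- p

  p <- file.path(dir, "occurrences.csv")
  utils::write.csv(world@occurrences, p, row.names = FALSE)
  paths[["occurrences"]] <- p
  p <- file.path(dir, "plots.csv")
  utils::write.csv(world@plots, p, row.names = FALSE)
  paths[["plots"]] <- p
  p <- file.path(dir, "species.csv")
  utils::write.csv(world@species, p, row.names = FALSE)
  paths[["species"]] <- p
  p <- file.path(dir, "phylogeny.nwk")
  writeNewick(world@phylo, p)
  paths[["phylogeny"]] <- p

  manifest <- list(
    seed = world@seed,
    grid = list(lonMin = grid@lonMin, lonMax = grid@lonMax,
                latMin = grid@latMin, latMax = grid@latMax, res = grid@res),
    artifacts = lapply(stats::setNames(nm = names(paths)), function(nm)
      list(path = basename(paths[[nm]]),
           md5 = unname(tools::md5sum(paths[[nm]]))))
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
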
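#' Generate the synthetic environmental raster stack
#'
#' Builds the nine predictor layers plus elevation as smooth spatial fields:
#' a low-order latitudinal/elevational trend plus spatially correlated
#' (gaussian-smoothed) noise.  Mean annual temperature decreases with
#' absolute latitude and with elevation; precipitation decays away from the
#' equator; growing-season length and net primary productivity are derived
#' from temperature and precipitation so the layers co-vary the way climate
#' layers do.  Future scenarios add a configurable warming offset to the six
#' climate layers (default +3 degC on MAT, x0.8 on precipitation, with
#' consistent knock-on offsets); the three soil layers and elevation are kept
#' constant across scenarios.  A zero-delta scenario reproduces the current
#' climate exactly.
#'
#' @param grid a [GridSpec-class] with at least 20 x 20 cells.
#' @param seed integer seed (substream `"env"` of the world seed).
#' @param scenarios named list of scenario deltas, each a list with `dT`
#'   (degC added to MAT) and `dP` (multiplicative precipitation factor).
#' @param oceanFrac fraction of cells masked as water (no-data).
#' @param noiseSigma smoothing length (cells) of the correlated noise.
#' @return an [EnvStack-class].
#' @examples
#' env <- generateEnvStack(gridSpec(0, 20, 0, 20, 1), seed = 1)
#' names(envLayers(env))
#' @export
generateEnvStack <- function(grid, seed,
                             scenarios = list(ssp585 = list(dT = 3, dP = 0.8)),
                             oceanFrac = 0.1, noiseSigma = 3) {
  if (grid@nRows < 20 || grid@nCols < 20)
    stop("grid too small: the environmental generator needs at least 20 x 20 cells")
  withSubstream(seed, "env", {
    nr <- grid@nRows; nc <- grid@nCols
    latm <- matrix(cellCenters(grid)[, "lat"], nrow = nr, byrow = TRUE)
    noise <- function(sd = 1) gaussianSmooth(matrix(stats::rnorm(nr * nc, sd = sd), nr, nc), noiseSigma)

    elevation <- pmax(900 * noise(1) + 350 * noise(1), 0)
    mat <- 28 - 0.45 * abs(latm) - 6.5 * elevation / 1000 + 1.5 * noise(1)
    tseason <- pmax(2 + 0.12 * abs(latm) + 0.6 * noise(1), 0.5)
    prec <- pmax(2200 * exp(-abs(latm) / 35) + 350 * noise(1), 50)
    pseason <- pmin(pmax(45 + 18 * noise(1), 5), 100)
    gsl <- pmin(pmax(365 - 4.5 * pmax(abs(latm) - 10, 0) - 0.02 * elevation + 10 * noise(1), 0), 365)
    npp <- pmax(0.4 * prec * (mat + 12) / 40 + 60 * noise(1), 0)
    silt <- pmin(pmax(38 + 12 * noise(1), 2), 80)
    cf <- pmin(pmax(15 + 9 * noise(1), 0), 70)
    ph <- pmin(pmax(6.3 + 0.8 * noise(1), 4), 9)

    mfield <- gaussianSmooth(matrix(stats::rnorm(nr * nc), nr, nc), noiseSigma * 2)
    mask <- mfield > stats::quantile(mfield, oceanFrac)

    future <- lapply(scenarios, function(sc) {
      dT <- sc$dT; dP <- sc$dP
      list(
        mat = mat + dT,
        tseason = tseason + 0.5 * dT,
        prec = pmax(prec * dP, 0),
        pseason = pmin(pmax(pseason * (2 - dP), 0), 100),
        gsl = pmin(pmax(gsl + 8 * dT, 0), 365),
        npp = pmax(npp * (1 + 0.03 * dT) * sqrt(dP), 0)
      )
    })

    new("EnvStack", grid = grid,
        layers = list(mat = mat, tseason = tseason, prec = prec,
                      pseason = pseason, gsl = gsl, npp = npp,
                      silt = silt, cf = cf, ph = ph, elevation = elevation),
        future = future, mask = mask)
  })
}

#' Accessors for environmental stacks
#'
#' `envLayers()` returns the named list of current layers; `envLayer()` one
#' layer for a given scenario (`"current"` or a future scenario name), with
#' soil layers and elevation scenario-invariant; `envMask()` the land mask;
#' `envGrid()` the grid; `envScenarios()` the future scenario names.
#'
#' @param env an [EnvStack-class].
#' @param name layer name.
#' @param scenario `"current"` or one of `envScenarios(env)`.
#' @return matrices / names as described.
#' @export
envLayers <- function(env) env@layers

#' @rdname envLayers
#' @export
envLayer <- function(env, name, scenario = "current") {
  if (scenario == "current" || !(name %in% climateLayerNames()))
    return(env@layers[[name]])
  if (!scenario %in% names(env@future))
    stop("unknown scenario: ", scenario)
  env@future[[scenario]][[name]]
}

#' @rdname envLayers
#' @export
envMask <- function(env) env@mask

#' @rdname envLayers
#' @export
envGrid <- function(env) env@grid

#' @rdname envLayers
#' @export
envScenarios <- function(env) names(env@future)

# Predictor matrix (cells x 9) for a set of cells under a scenario.
predictorMatrix <- function(env, rows, cols, scenario = "current") {
  idx <- cbind(rows, cols)
  out <- vapply(predictorNames(),
                function(nm) envLayer(env, nm, scenario)[idx],
                numeric(length(rows)))
  out <- matrix(out, nrow = length(rows),
                dimnames = list(NULL, predictorNames()))
  out
}

setMethod("show", "EnvStack", function(object) {
  cat(sprintf("EnvStack: %d layers on %d x %d grid, %d land cells, scenarios: %s\n",
              length(object@layers), object@grid@nRows, object@grid@nCols,
              sum(object@mask),
              paste(names(object@future), collapse = ", ")))
})
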
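#' Pseudoabsence schedule
#'
#' Number of training presences and pseudoabsences as a function of the
#' number of spatially distinct observations, following the published
#' regimes: with at least 10,000 observations, 10,000 of each; between 1818
#' and 10,000, all observations and pseudoabsences up to the 20,000-point
#' cap; between 500 and 1818, ten pseudoabsences per observation; below
#' 500, a flat 5000 pseudoabsences so the region's environmental conditions
#' stay well represented.
#'
#' @param nObs number of distinct occupied cells after aggregation (>= 20).
#' @return list with `n_obs_training` and `n_PA_training`.
#' @examples
#' pseudoabsenceSchedule(300)    # 300 presences, 5000 pseudoabsences
#' pseudoabsenceSchedule(12000)  # capped at 10,000 + 10,000
#' @export
pseudoabsenceSchedule <- function(nObs) {
  if (nObs < 20) stop("species with fewer than 20 observations are ineligible")
  if (nObs >= 10000) list(n_obs_training = 10000, n_PA_training = 10000)
  else if (nObs >= 1818) list(n_obs_training = nObs, n_PA_training = 20000 - nObs)
  else if (nObs >= 500) list(n_obs_training = nObs, n_PA_training = 10 * nObs)
  else list(n_obs_training = nObs, n_PA_training = 5000)
}

#' Assemble a training set
#'
#' Presences are the species' occupied cells inside the range (subsampled
#' without replacement to the schedule's presence quota if over it);
#' pseudoabsences are drawn uniformly at random over unmasked, in-range
#' cells that hold no presence.  If fewer such cells exist than the
#' pseudoabsence quota, all of them are used with a warning.
#'
#' @param cells data.frame with `row`, `col`: the species' occupied cells.
#' @param range a [SpeciesRange-class].
#' @param env an [EnvStack-class].
#' @param schedule output of [pseudoabsenceSchedule()].
#' @param seed integer seed.
#' @return list with `presences`, `absences` (data.frames of `row`, `col`),
#'   `x` (predictor matrix), `y` (0/1 labels), `n_obs_training`,
#'   `n_PA_training`.
#' @export
sampleTraining <- function(cells, range, env, schedule, seed) {
  if (!any(range@cells)) stop("empty range polygon")
  withSubstream(seed, "training", {
    inRange <- range@cells & env@mask
    keep <- inRange[cbind(cells$row, cells$col)]
    pres <- cells[keep, c("row", "col"), drop = FALSE]
    if (nrow(pres) > schedule$n_obs_training)
      pres <- pres[sample.int(nrow(pres), schedule$n_obs_training), , drop = FALSE]
    presIdx <- (pres$col - 1L) * range@grid@nRows + pres$row
    candIdx <- setdiff(which(inRange), presIdx)
    if (length(candIdx) == 0) stop("no cells available for pseudoabsences")
    nPA <- schedule$n_PA_training
    if (length(candIdx) < nPA) {
      warning(sprintf("only %d cells available for %d pseudoabsences; using all",
                      length(candIdx), nPA))
      nPA <- length(candIdx)
      absIdx <- candIdx
    } else absIdx <- sample(candIdx, nPA)
    nr <- range@grid@nRows
    abs <- data.frame(row = (absIdx - 1L) %% nr + 1L,
                      col = (absIdx - 1L) %/% nr + 1L)
    x <- rbind(predictorMatrix(env, pres$row, pres$col),
               predictorMatrix(env, abs$row, abs$col))
    y <- c(rep(1L, nrow(pres)), rep(0L, nrow(abs)))
    list(presences = pres, absences = abs, x = x, y = y,
         n_obs_training = nrow(pres), n_PA_training = nrow(abs))
  })
}

#' Select predictors under the 10x observations rule
#'
#' Uses `k = min(9, floor(nObs / 10))` predictors, so the observation count
#' is always at least ten times the predictor count; species with at least
#' 90 observations use all nine.  When `k < 9`, predictors are ranked by
#' impurity importance from a single all-predictor random forest fit on the
#' training set, ties broken by the fixed predictor order.
#'
#' @param training output of [sampleTraining()] (or any list with `x`, `y`).
#' @param nObs number of distinct observations for the species.
#' @param seed integer seed for the ranking forest.
#' @return character vector of selected predictor names.
#' @export
selectPredictors <- function(training, nObs, seed = 1) {
  allPred <- colnames(training$x)
  k <- min(length(allPred), floor(nObs / 10))
  if (k >= length(allPred)) return(allPred)
  fit <- ranger::ranger(x = as.data.frame(training$x),
                        y = factor(training$y, levels = c(0, 1)),
                        num.trees = 500, importance = "impurity",
                        seed = substreamSeed(seed, "varimp"), num.threads = 1)
  imp <- fit$variable.importance[allPred]
  ord <- order(-imp, match(allPred, predictorNames()))
  allPred[sort(ord[seq_len(k)])]
}
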
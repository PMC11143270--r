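#' Default ensemble hyperparameters
#'
#' Two random forests and two gradient-boosted tree classifiers at
#' different complexity levels: RF-simple (200 trees, depth 5), RF-complex
#' (500 trees, unlimited depth), GBT-simple (100 rounds, depth 2),
#' GBT-complex (300 rounds, depth 5).
#'
#' @param ... overrides for individual members.
#' @return named list of member hyperparameter lists.
#' @export
ensembleHyper <- function(...) {
  h <- list(
    rf_simple = list(trees = 200, depth = 5),
    rf_complex = list(trees = 500, depth = 0),
    gbt_simple = list(rounds = 100, depth = 2, eta = 0.1),
    gbt_complex = list(rounds = 300, depth = 5, eta = 0.1)
  )
  over <- list(...)
  for (nm in names(over)) h[[nm]] <- utils::modifyList(h[[nm]], over[[nm]])
  h
}

fitMembers <- function(x, y, predictors, hyper, seed) {
  if (length(unique(y)) < 2) stop("single-class training set")
  xs <- x[, predictors, drop = FALSE]
  yf <- factor(y, levels = c(0, 1))
  rf <- function(h, nm) ranger::ranger(
    x = as.data.frame(xs), y = yf, probability = TRUE,
    num.trees = h$trees, max.depth = h$depth,
    seed = substreamSeed(seed, nm), num.threads = 1)
  gbt <- function(h, nm) xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = h$depth,
                  eta = h$eta, nthread = 1, seed = substreamSeed(seed, nm)),
    data = xgboost::xgb.DMatrix(xs, label = y), nrounds = h$rounds, verbose = 0)
  list(rf_simple = rf(hyper$rf_simple, "rf_simple"),
       rf_complex = rf(hyper$rf_complex, "rf_complex"),
       gbt_simple = gbt(hyper$gbt_simple, "gbt_simple"),
       gbt_complex = gbt(hyper$gbt_complex, "gbt_complex"))
}

memberProbs <- function(members, x, predictors) {
  xs <- x[, predictors, drop = FALSE]
  pr <- function(m) {
    if (inherits(m, "ranger")) {
      p <- stats::predict(m, data = as.data.frame(xs), num.threads = 1)$predictions
      p[, "1"]
    } else {
      stats::predict(m, xgboost::xgb.DMatrix(xs))
    }
  }
  vapply(members, pr, numeric(nrow(xs)))
}

#' Ensemble suitability: unweighted mean of the four member probabilities
#'
#' @param model an [EnsembleSDM-class].
#' @param x predictor matrix with the model's predictors as columns.
#' @return numeric vector of ensemble probabilities.
#' @export
predictEnsemble <- function(model, x) {
  rowMeans(memberProbs(model@members, x, model@predictors))
}

#' True skill statistic threshold scan
#'
#' Scans TSS(t) = sensitivity(t) + specificity(t) - 1 over the sorted
#' unique scores (classification rule: score >= t is a presence) and
#' returns the smallest maximising threshold.  The unique scores realise
#' every achievable confusion matrix, so the scan is exact.
#'
#' @param scores numeric probabilities.
#' @param labels 0/1 labels.
#' @return list with `threshold`, `TSS`, `sensitivity`, `specificity`.
#' @export
maxTssThreshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  u <- sort(unique(scores))
  g <- factor(match(scores, u), levels = seq_along(u))
  posAt <- vapply(split(labels, g), sum, numeric(1))
  cntAt <- vapply(split(labels, g), length, numeric(1))
  P <- sum(labels); N <- length(labels) - P
  if (P == 0 || N == 0) stop("need both classes to scan TSS")
  posGe <- rev(cumsum(rev(posAt)))
  negLt <- c(0, cumsum(cntAt - posAt))[seq_along(u)]
  tss <- posGe / P + negLt / N - 1
  i <- which.max(tss)  # first (= smallest threshold) among ties
  list(threshold = unname(u[i]), TSS = unname(tss[i]),
       sensitivity = unname(posGe[i] / P), specificity = unname(negLt[i] / N))
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) form, ties handled by midranks.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUC in [0, 1].
#' @export
aucFromScores <- function(scores, labels) {
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) stop("need both classes for AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Cross-validated max-TSS threshold
#'
#' Random 3-fold assignment (redrawn, boundedly, until every fold's
#' training split holds both classes); the ensemble is fitted on each
#' fold's complement and out-of-fold probabilities are pooled.  TSS is
#' scanned over the pooled unique scores and the smallest maximiser is the
#' binarisation threshold; AUC is computed on the same pooled scores.
#'
#' @param x predictor matrix.
#' @param y 0/1 labels.
#' @param predictors predictor names to use.
#' @param hyper [ensembleHyper()] list.
#' @param kFolds number of folds.
#' @param seed integer seed.
#' @param maxRetries fold-assignment retries before giving up.
#' @return list with `threshold`, `TSS`, `AUC`, `oof` (pooled out-of-fold
#'   probabilities) and `folds`.
#' @export
optimizeThresholdCV <- function(x, y, predictors, hyper = ensembleHyper(),
                                kFolds = 3, seed = 1, maxRetries = 20) {
  n <- length(y)
  withSubstream(seed, "cvfolds", {
    folds <- NULL
    for (try in seq_len(maxRetries)) {
      f <- sample(rep_len(seq_len(kFolds), n))
      ok <- all(vapply(seq_len(kFolds), function(k)
        length(unique(y[f != k])) == 2 && sum(f == k) > 0, logical(1)))
      if (ok) { folds <- f; break }
    }
    if (is.null(folds)) stop("could not draw folds with both classes present")
    oof <- numeric(n)
    for (k in seq_len(kFolds)) {
      tr <- folds != k
      members <- fitMembers(x[tr, , drop = FALSE], y[tr], predictors, hyper,
                            seed = substreamSeed(seed, paste0("fold", k)))
      oof[!tr] <- rowMeans(memberProbs(members, x[!tr, , drop = FALSE], predictors))
    }
    scan <- maxTssThreshold(oof, y)
    list(threshold = scan$threshold, TSS = scan$TSS,
         AUC = aucFromScores(oof, y), oof = oof, folds = folds)
  })
}

#' Fit the four-member ensemble with a cross-validated threshold
#'
#' Selects predictors under the 10x rule, finds the max-TSS threshold by
#' cross-validation, then refits the four members on the full training set.
#'
#' @param training output of [sampleTraining()].
#' @param nObs number of distinct observations (drives predictor count).
#' @param hyper [ensembleHyper()] list.
#' @param seed integer seed.
#' @param speciesId species id recorded on the model.
#' @param kFolds cross-validation folds.
#' @return an [EnsembleSDM-class].
#' @export
fitEnsemble <- function(training, nObs, hyper = ensembleHyper(), seed = 1,
                        speciesId = "sp", kFolds = 3) {
  predictors <- selectPredictors(training, nObs, seed = seed)
  cv <- optimizeThresholdCV(training$x, training$y, predictors, hyper,
                            kFolds = kFolds, seed = seed)
  members <- fitMembers(training$x, training$y, predictors, hyper,
                        seed = substreamSeed(seed, "final"))
  new("EnsembleSDM", speciesId = speciesId, members = members,
      predictors = predictors, threshold = cv$threshold,
      cvMetrics = list(TSS = cv$TSS, AUC = cv$AUC),
      schedule = list(n_obs_training = training$n_obs_training,
                      n_PA_training = training$n_PA_training))
}

setMethod("show", "EnsembleSDM", function(object) {
  cat(sprintf("EnsembleSDM %s: %d predictors, threshold %.3f, CV TSS %.3f, CV AUC %.3f\n",
              object@speciesId, length(object@predictors), object@threshold,
              object@cvMetrics$TSS, object@cvMetrics$AUC))
})
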
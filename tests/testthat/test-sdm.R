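test_that("the pseudoabsence schedule reproduces every published regime", {
  expect_equal(pseudoabsenceSchedule(12000),
               list(n_obs_training = 10000, n_PA_training = 10000))
  expect_equal(pseudoabsenceSchedule(10000),
               list(n_obs_training = 10000, n_PA_training = 10000))
  expect_equal(pseudoabsenceSchedule(9999),
               list(n_obs_training = 9999, n_PA_training = 10001))
  expect_equal(pseudoabsenceSchedule(1818),
               list(n_obs_training = 1818, n_PA_training = 18182))
  expect_equal(pseudoabsenceSchedule(1817),
               list(n_obs_training = 1817, n_PA_training = 18170))
  expect_equal(pseudoabsenceSchedule(500),
               list(n_obs_training = 500, n_PA_training = 5000))
  expect_equal(pseudoabsenceSchedule(499),
               list(n_obs_training = 499, n_PA_training = 5000))
  expect_equal(pseudoabsenceSchedule(300),
               list(n_obs_training = 300, n_PA_training = 5000))
  expect_equal(pseudoabsenceSchedule(20),
               list(n_obs_training = 20, n_PA_training = 5000))
  expect_error(pseudoabsenceSchedule(19), "ineligible")
  # cap property over the whole eligible domain
  for (n in c(20:30, 499:501, 1817:1819, 9999:10001, 50000)) {
    s <- pseudoabsenceSchedule(n)
    expect_lte(s$n_obs_training + s$n_PA_training, 20000)
  }
})

test_that("predictor count follows the 10x rule with importance ranking", {
  mkTraining <- function(n, sep = FALSE, seed = 1) {
    set.seed(seed)
    x <- matrix(rnorm(2 * n * 9), ncol = 9,
                dimnames = list(NULL, predictorNames()))
    y <- rep(c(1L, 0L), each = n)
    if (sep) x[, "gsl"] <- y * 10 + rnorm(2 * n, sd = 0.01)  # separates classes
    list(x = x, y = y)
  }
  expect_length(selectPredictors(mkTraining(60), nObs = 25), 2)   # 20-29 obs: two
  expect_length(selectPredictors(mkTraining(60), nObs = 89), 8)
  expect_length(selectPredictors(mkTraining(60), nObs = 90), 9)   # >= 90: all nine
  expect_length(selectPredictors(mkTraining(60), nObs = 200), 9)
  # a perfectly separating predictor always ranks first
  sel <- selectPredictors(mkTraining(15, sep = TRUE), nObs = 30)
  expect_length(sel, 3)
  expect_true("gsl" %in% sel)
})

test_that("training sets respect range containment, quotas and exhaustion", {
  f <- fixtureFit()
  w <- f$world; env <- worldEnv(w)
  tr <- f$training
  inRange <- rangeCells(f$range) & envMask(env)
  expect_true(all(inRange[cbind(tr$presences$row, tr$presences$col)]))
  expect_true(all(inRange[cbind(tr$absences$row, tr$absences$col)]))
  # no pseudoabsence on a presence cell
  pk <- paste(tr$presences$row, tr$presences$col)
  ak <- paste(tr$absences$row, tr$absences$col)
  expect_length(intersect(pk, ak), 0)
  expect_lte(tr$n_obs_training + tr$n_PA_training, 20000)
  # fixed seed reproduces the sample exactly
  sched <- pseudoabsenceSchedule(nrow(f$cells))
  tr2 <- suppressWarnings(sampleTraining(f$cells, f$range, env, sched, seed = 9))
  expect_identical(tr$x, tr2$x)
  expect_identical(tr$absences, tr2$absences)
  # exhaustion: more pseudoabsences requested than cells exist
  expect_warning(
    trX <- sampleTraining(f$cells, f$range, env, sched, seed = 1),
    "using all")
})

test_that("max-TSS scan matches hand-computed and simulated references", {
  # worked six-point set, scanned exhaustively by hand: threshold 0.4, TSS 1
  sc <- c(0.1, 0.2, 0.4, 0.3, 0.8, 0.9)
  lb <- c(0, 0, 1, 0, 1, 1)
  res <- maxTssThreshold(sc, lb)
  expect_equal(res$threshold, 0.4)
  expect_equal(res$TSS, 1)
  # perfect scores: threshold at the smallest positive score
  resP <- maxTssThreshold(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(resP$TSS, 1)
  expect_lte(resP$threshold, 1)
  # labels independent of scores: TSS near 0, AUC near 1/2
  set.seed(4)
  scR <- runif(10000); lbR <- rbinom(10000, 1, 0.5)
  expect_lt(abs(maxTssThreshold(scR, lbR)$TSS), 0.05)
  expect_lt(abs(aucFromScores(scR, lbR) - 0.5), 0.05)
})

test_that("AUC agrees with the ROC-curve reference implementation", {
  set.seed(2)
  sc <- round(runif(300), 2)  # ties included
  lb <- rbinom(300, 1, plogis(4 * sc - 2))
  expect_equal(aucFromScores(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("ensemble probability is the member mean and bounded by members", {
  f <- fixtureFit()
  m <- f$model
  idx <- which(rangeCells(f$range) & envMask(worldEnv(f$world)), arr.ind = TRUE)
  idx <- idx[seq_len(min(200, nrow(idx))), , drop = FALSE]
  x <- treeAtlas:::predictorMatrix(worldEnv(f$world), idx[, 1], idx[, 2])
  probs <- treeAtlas:::memberProbs(m@members, x, m@predictors)
  ens <- predictEnsemble(m, x)
  expect_equal(ens, rowMeans(probs), tolerance = 1e-12)
  expect_true(all(ens >= apply(probs, 1, min) - 1e-12))
  expect_true(all(ens <= apply(probs, 1, max) + 1e-12))
})

test_that("a linearly separable toy problem gives perfect cross-validated skill", {
  set.seed(6)
  n <- 120
  x <- matrix(rnorm(n * 9), ncol = 9, dimnames = list(NULL, predictorNames()))
  y <- rep(c(0L, 1L), length.out = n)
  x[, "mat"] <- ifelse(y == 1, 2, -2) + rnorm(n, sd = 0.1)  # wide margin
  cv <- optimizeThresholdCV(x, y, predictorNames(), kFolds = 3, seed = 2)
  expect_equal(cv$TSS, 1)
  expect_equal(cv$AUC, 1)
  expect_error(treeAtlas:::fitMembers(x, rep(1L, n), predictorNames(),
                                      ensembleHyper(), seed = 1),
               "single-class")
})

test_that("prediction clips to the range, obeys the tie rule and zero-delta identity", {
  f <- fixtureFit()
  w <- f$world; env <- worldEnv(w)
  maps <- f$maps
  outside <- !(rangeCells(f$range) & envMask(env))
  expect_true(all(is.na(maps$suitability[outside])))
  expect_true(all(is.na(maps$binary[outside])))
  inside <- !is.na(maps$suitability)
  expect_true(all(maps$suitability[inside] >= 0 & maps$suitability[inside] <= 1))
  # tie rule: probability exactly at the threshold is a presence
  expect_equal(maps$binary[inside], as.numeric(maps$suitability[inside] >= f$model@threshold))
  expect_error(predictAndBinarize(f$model, env, f$range, "nosuch"), "unknown scenario")
  # a zero-delta future gives bit-identical maps
  cfg0 <- tinyWorldConfig(scenarios = list(flat = list(dT = 0, dP = 1)))
  w0 <- makeWorld(seed = 42, cfg0)
  env0 <- worldEnv(w0)
  agg0 <- aggregateToGrid(mergeOccurrences(list(worldOccurrences(w0)),
                                           w0@species$species_id),
                          envGrid(env0), envMask(env0))
  n0 <- speciesCellCounts(agg0)
  sp0 <- names(n0)[which(n0 >= 50)[1]]
  cells0 <- agg0[agg0$species_id == sp0, c("row", "col")]
  rg0 <- buildGeographicRange(worldRegions(w0), nativeCountries(w0, sp0),
                              cells0, speciesId = sp0)
  tr0 <- suppressWarnings(sampleTraining(cells0, rg0, env0,
                                         pseudoabsenceSchedule(nrow(cells0)),
                                         seed = 3))
  m0 <- fitEnsemble(tr0, nrow(cells0), seed = 3, speciesId = sp0)
  nowM <- predictAndBinarize(m0, env0, rg0, "current")
  futM <- predictAndBinarize(m0, env0, rg0, "flat")
  expect_identical(nowM$suitability, futM$suitability)
  expect_identical(nowM$binary, futM$binary)
})

test_that("plot evaluation builds the right confusion matrix and skip rule", {
  g <- gridSpec(0, 20, 0, 20, 1)
  rg <- new("SpeciesRange", speciesId = "t", grid = g,
            cells = matrix(TRUE, 20, 20),
            geometry = list(),
            provenance = list(n_obs_used = 0L,
                              ecoregions_included = character(0),
                              aggregated = FALSE))
  binary <- matrix(0, 20, 20)
  # plots laid out one per cell along row 10 (lat 10.5): 8 TP, 2 FN, 3 FP, 7 TN
  plan <- data.frame(pred = rep(c(1, 0, 1, 0), c(8, 2, 3, 7)),
                     present = rep(c(TRUE, TRUE, FALSE, FALSE), c(8, 2, 3, 7)))
  plan$lon <- seq_len(nrow(plan)) - 0.5
  plan$lat <- 10.5
  idx <- cellIndex(g, plan$lon, plan$lat)
  binary[cbind(idx$row, idx$col)] <- plan$pred
  ev <- evaluatePlots(binary, plan, rg)
  expect_equal(ev[c("TP", "FN", "FP", "TN")], list(TP = 8, FN = 2, FP = 3, TN = 7))
  expect_equal(ev$recall, 0.8)
  expect_equal(ev$precision, 8 / 11)
  expect_equal(ev$TSS, 0.8 + 0.7 - 1)
  expect_equal(ev$FPR, 0.3)
  expect_equal(ev$FNR, 0.2)
  # perfect agreement
  binP <- binary
  evP <- evaluatePlots(binP, transform(plan, present = pred == 1), rg)
  expect_equal(evP$TSS, 1); expect_equal(evP$precision, 1); expect_equal(evP$recall, 1)
  # fewer than five in-range presences: species skipped
  few <- plan[c(1:4, 11:20), ]
  expect_null(evaluatePlots(binary, few, rg))
  # plots outside the range are excluded
  rg2 <- rg; rg2@cells[idx$row[1], idx$col[1]] <- FALSE
  ev2 <- evaluatePlots(binary, plan, rg2)
  expect_equal(ev2$TP, 7)
})

test_that("intersection over union follows its set definition", {
  a <- matrix(c(1, 1, 0, NA), 2, 2)
  expect_equal(iouOverlap(a, a), 1)
  b <- matrix(c(0, 0, 1, NA), 2, 2)
  expect_equal(iouOverlap(a, b), 0)
  cM <- matrix(c(1, 1, 0, 0), 2, 2)
  dM <- matrix(c(1, 0, 1, 0), 2, 2)  # |A|=|B|=2, overlap 1
  expect_equal(iouOverlap(cM, dM), 1 / 3)
  z <- matrix(0, 2, 2)
  expect_equal(as.numeric(iouOverlap(z, z)), 0)
  expect_true(attr(iouOverlap(z, z), "empty_union"))
  expect_error(iouOverlap(a, matrix(0, 3, 3)), "different grids")
})
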
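# Build a small community matrix + env from the shared fixture world.
fixtureCommunity <- function() {
  if (is.null(.fixtures$cm)) {
    w <- fixtureWorld()
    env <- worldEnv(w)
    bins <- lapply(worldSpecies(w), function(sp) {
      occ <- w@occupancy[[sp]]
      ifelse(envMask(env), as.numeric(occ), NA)  # realised occupancy as maps
    })
    names(bins) <- worldSpecies(w)
    .fixtures$cm <- buildCommunityMatrix(bins, env, coarseCellKm = 250)
  }
  .fixtures$cm
}

test_that("community matrix sampling follows the point-query and drop rules", {
  w <- fixtureWorld()
  env <- worldEnv(w); g <- envGrid(env)
  everywhere <- ifelse(envMask(env), 1, NA)
  nowhere <- ifelse(envMask(env), 0, NA)
  cm <- buildCommunityMatrix(list(all = everywhere, none = nowhere), env,
                             coarseCellKm = 300)
  inc <- communityIncidence(cm)
  # one species covering everything: an all-ones column
  expect_true(all(inc[, "all"] == 1))
  # a species absent everywhere keeps its all-zero column
  expect_true(all(inc[, "none"] == 0))
  expect_true("none" %in% colnames(inc))
  # sites are only dropped by empty rows or masked centres
  sites <- communitySites(cm)
  expect_true(all(envMask(env)[cbind(sites$row, sites$col)]))
  # coarse-cell centres on no-data cells are dropped
  envAll <- env; envAll@mask[] <- TRUE
  cmAll <- buildCommunityMatrix(list(all = matrix(1, g@nRows, g@nCols)),
                                envAll, coarseCellKm = 300)
  expect_gt(nrow(communitySites(cmAll)), nrow(sites))
  expect_error(buildCommunityMatrix(list(none = nowhere), env, 300),
               "no site")
})

test_that("Sorensen distances follow the 1 - 2a/(2a+b+c) formula", {
  m <- rbind(s1 = c(1, 1, 0, 0), s2 = c(1, 1, 0, 0),
             s3 = c(0, 0, 1, 1), s4 = c(0, 1, 1, 0))
  colnames(m) <- paste0("sp", 1:4)
  d <- as.matrix(sorensenDistances(m))
  expect_equal(d["s1", "s2"], 0)            # identical sites
  expect_equal(d["s1", "s3"], 1)            # disjoint sites
  expect_equal(d["s2", "s4"], 0.5)          # {s1,s2} vs {s2,s3}
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_error(sorensenDistances(m[1, , drop = FALSE]), "at least 2")
})

test_that("NMDS embeds Euclidean data, reports honest stress, never worsens its start", {
  set.seed(31)
  pts <- matrix(rnorm(60 * 3), 60, 3)
  dEuc <- dist(pts)
  fit <- runNMDS(dEuc, nAxes = 3, seed = 1, nStarts = 5)
  expect_lt(fit$stress, 1e-3)  # a perfect 3-D embedding exists
  expect_lte(fit$stress, fit$metricStartStress + 1e-9)
  # reported stress equals an independent stress-1 recomputation via
  # pool-adjacent-violators on the returned configuration
  expect_equal(fit$stress, treeAtlas:::stress1(dEuc, fit$scores),
               tolerance = 1e-8)
  # stress is invariant to rotation/translation of the configuration
  theta <- 0.7
  rot <- diag(3); rot[1:2, 1:2] <- matrix(c(cos(theta), sin(theta),
                                            -sin(theta), cos(theta)), 2)
  moved <- sweep(fit$scores %*% rot, 2, c(5, -2, 1), "+")
  expect_equal(treeAtlas:::stress1(dEuc, moved),
               treeAtlas:::stress1(dEuc, fit$scores), tolerance = 1e-10)
  # non-Euclidean community distances: still honest stress accounting
  cm <- fixtureCommunity()
  dS <- sorensenDistances(cm)
  fitS <- suppressWarnings(runNMDS(dS, nAxes = 3, seed = 2, nStarts = 8))
  expect_gte(fitS$stress, 0); expect_lte(fitS$stress, 1)
  expect_lte(fitS$stress, fitS$metricStartStress + 1e-9)
})

test_that("branch-weighted Hellinger PCA reduces to plain Hellinger PCA on a star tree", {
  set.seed(12)
  nSite <- 20; nSp <- 8
  m <- matrix(rbinom(nSite * nSp, 1, 0.45), nSite, nSp,
              dimnames = list(NULL, paste0("sp", seq_len(nSp))))
  m[rowSums(m) == 0, 1] <- 1
  star <- ape::stree(nSp, type = "star")
  star$tip.label <- colnames(m)
  star$edge.length <- rep(1, nrow(star$edge))
  evo <- evoPCAHellinger(m, star, nAxes = 3)
  # oracle: ordinary Hellinger transform + centred PCA of the species matrix
  hel <- sqrt(m / rowSums(m))
  pc <- prcomp(hel, center = TRUE, scale. = FALSE)
  oracle <- pc$x[, 1:3]
  # compare 3-D score subspaces through principal angles
  q1 <- qr.Q(qr(evo$scores)); q2 <- qr.Q(qr(oracle))
  angles <- acos(pmin(1, svd(crossprod(q1, q2))$d))
  expect_lt(max(angles), 1e-6)
  expect_true(all(diff(evo$varianceFractions) <= 1e-12))
  expect_lte(sum(evo$varianceFractions), 1 + 1e-12)
})

test_that("phylogenetic ordination handles duplicates, errors and real trees", {
  w <- fixtureWorld()
  cm <- fixtureCommunity()
  evo <- evoPCAHellinger(cm, worldPhylo(w), nAxes = 3)
  expect_equal(nrow(evo$scores), nrow(communityIncidence(cm)))
  # two sites with identical incidence get identical score rows
  inc <- communityIncidence(cm)
  dup <- rbind(inc, inc[3, , drop = FALSE])
  evoD <- evoPCAHellinger(dup, worldPhylo(w), nAxes = 3)
  expect_equal(evoD$scores[3, ], evoD$scores[nrow(dup), ], tolerance = 1e-12)
  # species missing from the tree is named in the error
  bad <- inc; colnames(bad)[1] <- "ghost"
  expect_error(evoPCAHellinger(bad, worldPhylo(w)), "ghost")
})

test_that("RGB mapping anchors the 10th/90th percentiles and clips outside", {
  set.seed(5)
  sc <- cbind(sort(rnorm(101)), rnorm(101), rnorm(101))
  rgb <- rgbMap(sc)
  lo <- quantile(sc[, 1], 0.10, type = 7); hi <- quantile(sc[, 1], 0.90, type = 7)
  iLo <- which.min(abs(sc[, 1] - lo))
  expect_equal(unname(rgb[iLo, 1]), 0, tolerance = 1e-6)
  expect_equal(rgb[sc[, 1] > hi, 1], rep(1, sum(sc[, 1] > hi)))
  expect_true(all(rgb >= 0 & rgb <= 1))
  # monotone: channel ordering preserves axis ordering up to clipping
  mid <- sc[, 1] > lo & sc[, 1] < hi
  expect_true(all(diff(rgb[mid, 1]) >= 0))
  expect_warning(rgbC <- rgbMap(cbind(1, sc[, 2:3])), "constant")
  expect_true(all(rgbC[, 1] == 0.5))
})

test_that("IQR outlier filtering is a single-pass quartile rule", {
  sc <- cbind(c(rep(0, 19), 100), rnorm(20))
  keep <- iqrOutlierFilter(sc)
  expect_false(keep[20])       # the 100 is outside [Q1-IQR, Q3+IQR]
  expect_true(all(keep[1:19]))
  # constant scores: nothing removed
  expect_true(all(iqrOutlierFilter(cbind(rep(2, 10), rep(3, 10)))))
  expect_error(iqrOutlierFilter(matrix(0, 3, 2)), "at least 4")
})

test_that("silhouette-based k selection recovers well-separated blobs", {
  set.seed(9)
  blob <- function(cx) cbind(rnorm(40, cx, 1), rnorm(40, 0, 1), rnorm(40, 0, 1))
  sc <- rbind(blob(0), blob(20))  # 10 sigma apart
  cl <- clusterBySilhouette(sc, kRange = 2:6, seed = 4)
  expect_equal(cl$bestK, 2L)
  expect_gt(max(cl$silhouettes), 0.7)
  # labels are a partition of all filtered sites
  expect_length(cl$labels, nrow(sc))
  expect_true(all(cl$labels %in% 1:2))
  # the two blobs are exactly the two clusters
  expect_equal(length(unique(cl$labels[1:40])), 1L)
  expect_equal(length(unique(cl$labels[41:80])), 1L)
})

test_that("RDA and variation partitioning recover exact and null structure", {
  set.seed(14)
  n <- 300
  envDf <- as.data.frame(matrix(rnorm(n * 9), n, 9,
                                dimnames = list(NULL, predictorNames())))
  # scores exactly linear in the predictors: everything explained
  B <- matrix(rnorm(9 * 3), 9, 3)
  scLin <- as.matrix(envDf) %*% B
  vpL <- rdaVarpart(scLin, envDf)
  expect_gt(vpL$total_R2_adj, 0.999)
  # independent scores, larger n: adjusted R-squared near zero
  env2 <- as.data.frame(matrix(rnorm(2000 * 9), 2000, 9,
                               dimnames = list(NULL, predictorNames())))
  vp0 <- rdaVarpart(matrix(rnorm(2000 * 3), 2000, 3), env2)
  expect_lt(abs(vp0$total_R2_adj), 0.05)
  # partition identity (up to adjustment negativity, which is flagged)
  parts <- vpL$climate_only + vpL$soil_only + vpL$shared
  expect_lte(parts, vpL$total_R2_adj + 0.01)
  # collinear predictors are dropped with a warning
  env3 <- envDf; env3$cf <- env3$silt
  expect_warning(rdaVarpart(scLin, env3), "collinear")
})

test_that("environmental PCA is standardised and permutation-invariant", {
  cm <- fixtureCommunity()
  envDf <- siteEnvironment(cm, worldEnv(fixtureWorld()))
  p <- envPCA(envDf)
  expect_gte(p$varianceExplained[1], p$varianceExplained[2])
  perm <- envPCA(envDf[, rev(seq_len(ncol(envDf)))])
  expect_equal(abs(p$scores), abs(perm$scores), tolerance = 1e-8)
  # two perfectly correlated variables only: axis 1 explains everything
  x <- rnorm(50)
  p2 <- envPCA(data.frame(a = x, b = 2 * x + 3))
  expect_equal(p2$varianceExplained[1], 1)
  expect_error(envPCA(envDf[1:2, ]), "at least 3")
})
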
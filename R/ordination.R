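#' Build the equal-area community matrix
#'
#' Overlays an equal-area coarse grid (constant longitude step, rows of
#' constant sin-latitude step, so every coarse cell has the same spherical
#' area, ~`coarseCellKm` squared) and samples each species' binary map at
#' the coarse-cell centre (nearest predictor cell, point query).  Sites
#' whose centre falls on a masked (no-data) predictor cell are dropped, as
#' are sites where no species is present; all-zero species columns are
#' retained.
#'
#' @param binaries named list of 0/1/NA matrices (one per species).
#' @param env the [EnvStack-class] the binaries live on.
#' @param coarseCellKm target coarse cell edge length in km.
#' @return a [CommunityMatrix-class]; `sites` carries the predictor-grid
#'   `row`/`col` of each site centre for later environment extraction.
#' @export
buildCommunityMatrix <- function(binaries, env, coarseCellKm = 100) {
  grid <- env@grid
  midLat <- (grid@latMin + grid@latMax) / 2
  dLonRad <- coarseCellKm / (EARTH_RADIUS_KM * max(0.05, cos(midLat * pi / 180)))
  dLon <- dLonRad * 180 / pi
  dSin <- coarseCellKm^2 / (EARTH_RADIUS_KM^2 * dLonRad)
  lonEdges <- seq(grid@lonMin, grid@lonMax, by = dLon)
  if (max(lonEdges) < grid@lonMax) lonEdges <- c(lonEdges, grid@lonMax)
  sinEdges <- seq(sin(grid@latMin * pi / 180), sin(grid@latMax * pi / 180), by = dSin)
  if (max(sinEdges) < sin(grid@latMax * pi / 180))
    sinEdges <- c(sinEdges, sin(grid@latMax * pi / 180))
  lonCtr <- (lonEdges[-1] + lonEdges[-length(lonEdges)]) / 2
  latCtr <- asin((sinEdges[-1] + sinEdges[-length(sinEdges)]) / 2) * 180 / pi
  pts <- expand.grid(lon = lonCtr, lat = latCtr)
  idx <- cellIndex(grid, pts$lon, pts$lat)
  ok <- !is.na(idx$row)
  ok[ok] <- env@mask[cbind(idx$row[ok], idx$col[ok])]
  pts <- pts[ok, , drop = FALSE]; idx <- idx[ok, , drop = FALSE]
  inc <- vapply(binaries, function(b) {
    v <- b[cbind(idx$row, idx$col)]
    as.numeric(!is.na(v) & v == 1)
  }, numeric(nrow(idx)))
  inc <- matrix(inc, nrow = nrow(idx), dimnames = list(NULL, names(binaries)))
  nonEmpty <- rowSums(inc) > 0
  if (!any(nonEmpty)) stop("no site holds any species")
  sites <- data.frame(site_id = sprintf("site%04d", seq_len(sum(nonEmpty))),
                      lon = pts$lon[nonEmpty], lat = pts$lat[nonEmpty],
                      row = idx$row[nonEmpty], col = idx$col[nonEmpty])
  new("CommunityMatrix", sites = sites,
      incidence = inc[nonEmpty, , drop = FALSE])
}

#' @rdname buildCommunityMatrix
#' @param cm a [CommunityMatrix-class].
#' @export
communityIncidence <- function(cm) cm@incidence

#' @rdname buildCommunityMatrix
#' @export
communitySites <- function(cm) cm@sites

setMethod("show", "CommunityMatrix", function(object) {
  cat(sprintf("CommunityMatrix: %d sites x %d species, fill %.1f%%\n",
              nrow(object@incidence), ncol(object@incidence),
              100 * mean(object@incidence)))
})

#' Extract predictors at community-matrix sites
#'
#' @param cm a [CommunityMatrix-class] built by [buildCommunityMatrix()].
#' @param env the matching [EnvStack-class].
#' @return data.frame of the nine predictors at each site.
#' @export
siteEnvironment <- function(cm, env) {
  as.data.frame(predictorMatrix(env, cm@sites$row, cm@sites$col))
}

#' Sorensen distances between sites
#'
#' `d(i, j) = 1 - 2|A n B| / (|A| + |B|)` on incidence sets (binary
#' Bray-Curtis), via [vegan::vegdist()].
#'
#' @param cm a [CommunityMatrix-class] or a 0/1 matrix.
#' @return a `dist` object.
#' @export
sorensenDistances <- function(cm) {
  m <- if (is(cm, "CommunityMatrix")) cm@incidence else cm
  if (nrow(m) < 2) stop("need at least 2 sites")
  vegan::vegdist(m, method = "bray", binary = TRUE)
}

# Kruskal stress-1 of a configuration against dissimilarities, with the
# monotone (primary-ties) regression recomputed by pool-adjacent-violators.
# Used as the independent check that the NMDS engine reports the stress of
# the configuration it returns.
stress1 <- function(d, scores) {
  dhat <- as.vector(stats::dist(scores))
  dobs <- as.vector(d)
  ord <- order(dobs, dhat)  # primary tie treatment: ties free, sorted by dhat
  y <- dhat[ord]
  fit <- pavaFit(y)
  sqrt(sum((dhat[ord] - fit)^2) / sum(dhat^2))
}

# Pool-adjacent-violators for a nondecreasing least-squares fit.
pavaFit <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  val <- y; wt <- w; idx <- integer(n); nb <- 0L
  sizes <- integer(n)
  for (i in seq_len(n)) {
    nb <- nb + 1L
    val[nb] <- y[i]; wt[nb] <- w[i]; sizes[nb] <- 1L
    while (nb > 1 && val[nb - 1] > val[nb]) {
      tot <- wt[nb - 1] + wt[nb]
      val[nb - 1] <- (wt[nb - 1] * val[nb - 1] + wt[nb] * val[nb]) / tot
      wt[nb - 1] <- tot; sizes[nb - 1] <- sizes[nb - 1] + sizes[nb]
      nb <- nb - 1L
    }
  }
  rep(val[seq_len(nb)], sizes[seq_len(nb)])
}

#' Non-metric multidimensional scaling
#'
#' Minimises Kruskal stress-1 (primary tie treatment) with
#' [vegan::monoMDS()], from a metric-scaling (classical MDS) start plus
#' `nStarts` random starts, keeping the best configuration; scores are
#' centred and rotated to principal axes.
#'
#' @param d a `dist` of site dissimilarities.
#' @param nAxes number of ordination axes.
#' @param seed integer seed for the random starts.
#' @param nStarts number of random starts in addition to the metric start.
#' @param maxIter iteration cap per start.
#' @param tol stress-ratio convergence tolerance.
#' @return list with `kind = "NMDS"`, `scores` (sites x nAxes), `stress`,
#'   `converged`, and `metricStartStress` (stress-1 of the classical-MDS
#'   initial configuration).
#' @export
runNMDS <- function(d, nAxes = 3, seed = 1, nStarts = 20, maxIter = 500,
                    tol = 1e-6) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  kUse <- min(nAxes, n - 1)  # an embedding of n points needs at most n - 1 axes
  init <- suppressWarnings(stats::cmdscale(d, k = kUse))
  if (ncol(init) < kUse)
    init <- cbind(init, matrix(0, n, kUse - ncol(init)))
  withSubstream(seed, "nmds", {
    run1 <- function(y) vegan::monoMDS(d, y = y, k = kUse, model = "global",
                                       maxit = maxIter, sratmax = 1 - tol)
    best <- run1(init)
    for (s in seq_len(nStarts)) {
      y0 <- matrix(stats::rnorm(n * kUse), n, kUse)
      fit <- run1(y0)
      if (fit$stress < best$stress) best <- fit
    }
    sc <- scale(best$points, center = TRUE, scale = FALSE)
    rot <- stats::prcomp(sc, center = FALSE, scale. = FALSE)
    scores <- rot$x[, seq_len(kUse), drop = FALSE]
    if (kUse < nAxes)
      scores <- cbind(scores, matrix(0, n, nAxes - kUse))
    colnames(scores) <- paste0("NMDS", seq_len(nAxes))
    conv <- is.null(best$icause) || best$icause != 1  # 1 = hit iteration cap
    if (!conv) warning("NMDS did not converge in any start; best configuration returned")
    list(kind = "NMDS", scores = scores, stress = best$stress,
         converged = conv, metricStartStress = stress1(d, init))
  })
}

#' Phylogenetic ordination: branch-weighted Hellinger PCA
#'
#' Expands the site-by-species incidence matrix to site-by-branch
#' abundances (each branch accumulates the incidences of the tips that
#' descend from it), applies a branch-length-weighted Hellinger transform
#' `M[i, b] = sqrt(l_b * x[i, b] / X_i)` with site totals
#' `X_i = sum_b l_b * x[i, b]`, and performs a column-centred PCA.  Squared
#' Euclidean distances between transformed rows are the branch-length-
#' weighted Hellinger phylogenetic dissimilarities; for a star phylogeny
#' with equal branch lengths the ordination reduces (up to a constant
#' scale) to a plain Hellinger-transform PCA of the species matrix.
#'
#' @param cm a [CommunityMatrix-class] or 0/1 matrix with species columns.
#' @param phylo an [ape::phylo] tree containing every species as a tip
#'   (extra tips are pruned).
#' @param nAxes number of axes to return.
#' @return list with `kind = "evoPCA"`, `scores`, `varianceFractions`
#'   (per returned axis, of total variance, non-increasing).
#' @export
evoPCAHellinger <- function(cm, phylo, nAxes = 3) {
  m <- if (is(cm, "CommunityMatrix")) cm@incidence else cm
  sp <- colnames(m)
  missing <- setdiff(sp, phylo$tip.label)
  if (length(missing))
    stop("species missing from the phylogeny: ", paste(missing, collapse = ", "))
  if (length(setdiff(phylo$tip.label, sp)))
    phylo <- ape::drop.tip(phylo, setdiff(phylo$tip.label, sp))
  ntip <- length(phylo$tip.label)
  tipCols <- match(phylo$tip.label, sp)
  desc <- phangorn::Descendants(phylo, phylo$edge[, 2], type = "tips")
  B <- vapply(desc, function(tips) {
    cols <- tipCols[tips]
    if (length(cols) == 1) m[, cols] else rowSums(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  B <- matrix(B, nrow = nrow(m))
  l <- phylo$edge.length
  X <- as.vector(B %*% l)
  if (any(X <= 0)) stop("site with zero branch-weighted total (all-zero row?)")
  M <- sqrt(sweep(B, 2, l, "*") / X)
  Mc <- scale(M, center = TRUE, scale = FALSE)
  sv <- svd(Mc)
  k <- min(nAxes, sum(sv$d > max(sv$d) * 1e-12))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  if (k < nAxes) scores <- cbind(scores, matrix(0, nrow(m), nAxes - k))
  colnames(scores) <- paste0("evoPCA", seq_len(nAxes))
  vf <- (sv$d^2 / sum(sv$d^2))[seq_len(nAxes)]
  vf[is.na(vf)] <- 0
  list(kind = "evoPCA", scores = scores, varianceFractions = vf)
}

#' Map ordination axes to RGB channels
#'
#' Each axis is linearly rescaled so its `pLo`-th percentile maps to 0 and
#' its `pHi`-th percentile to 1, clipping outside; a constant axis maps to
#' mid-channel with a warning.
#'
#' @param scores sites x 3 matrix.
#' @param pLo,pHi percentile anchors.
#' @return sites x 3 matrix of channel values in [0, 1].
#' @export
rgbMap <- function(scores, pLo = 10, pHi = 90) {
  stopifnot(ncol(scores) == 3)
  out <- apply(scores, 2, function(x) {
    lo <- quantile7(x, pLo / 100); hi <- quantile7(x, pHi / 100)
    if (hi <= lo) {
      warning("constant ordination axis mapped to mid-channel")
      return(rep(0.5, length(x)))
    }
    pmin(1, pmax(0, (x - lo) / (hi - lo)))
  })
  colnames(out) <- c("R", "G", "B")
  out
}

#' IQR outlier filter on ordination scores
#'
#' Single-pass rule: a site is removed iff any axis value falls outside
#' `[Q1 - IQR, Q3 + IQR]` for that axis (quartiles by linear interpolation,
#' computed once on the input, not recomputed after removals).
#'
#' @param scores sites x axes matrix.
#' @return logical vector, `TRUE` for retained sites.
#' @export
iqrOutlierFilter <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 4) stop("need at least 4 sites")
  keep <- rep(TRUE, nrow(scores))
  for (j in seq_len(ncol(scores))) {
    q <- quantile7(scores[, j], c(0.25, 0.75))
    iqr <- q[2] - q[1]
    keep <- keep & scores[, j] >= q[1] - iqr & scores[, j] <= q[2] + iqr
  }
  keep
}

#' K-means clustering with silhouette-based selection of k
#'
#' Runs k-means (multiple initialisations, fixed seed) on the joint
#' ordination axes for each candidate `k` and keeps the `k` with the
#' highest mean silhouette width; ties go to the smaller `k`.
#'
#' @param scores (filtered) sites x axes matrix.
#' @param kRange candidate numbers of clusters.
#' @param seed integer seed.
#' @param nInits k-means restarts per k.
#' @return list with `bestK`, `labels`, `silhouettes` (named by k).
#' @export
clusterBySilhouette <- function(scores, kRange = 2:6, seed = 1, nInits = 10) {
  scores <- as.matrix(scores)
  kRange <- kRange[kRange >= 2 & kRange <= nrow(scores) - 1]
  if (!length(kRange)) stop("no valid k in range")
  dd <- stats::dist(scores)
  sil <- stats::setNames(numeric(length(kRange)), kRange)
  labs <- vector("list", length(kRange))
  withSubstream(seed, "kmeans", {
    for (i in seq_along(kRange)) {
      cl <- stats::kmeans(scores, centers = kRange[i], nstart = nInits,
                          iter.max = 100)
      labs[[i]] <- cl$cluster
      sil[i] <- mean(cluster::silhouette(cl$cluster, dd)[, "sil_width"])
    }
  })
  best <- which.max(sil)  # first max = smallest k on ties
  list(bestK = kRange[best], labels = labs[[best]], silhouettes = sil)
}

#' Redundancy analysis and climate/soil variation partitioning
#'
#' RDA of the ordination scores on the standardised predictors (adjusted
#' R-squared), and variation partitioning over the six-climate and
#' three-soil blocks via [vegan::varpart()].  Collinear predictor columns
#' are dropped with a warning.
#'
#' @param scores sites x axes matrix.
#' @param envAtSites data.frame of the nine predictors at the same sites.
#' @return list with `total_R2_adj`, `climate_only`, `soil_only`, `shared`
#'   (adjusted fractions; `shared` can be slightly negative, flagged by
#'   `shared_negative`).
#' @export
rdaVarpart <- function(scores, envAtSites) {
  X <- scale(as.matrix(envAtSites))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    warning("dropping collinear predictors: ", paste(drop, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  clim <- X[, intersect(colnames(X), climateLayerNames()), drop = FALSE]
  soil <- X[, intersect(colnames(X), soilLayerNames()), drop = FALSE]
  total <- vegan::RsquareAdj(vegan::rda(scores, X))$adj.r.squared
  vp <- vegan::varpart(scores, clim, soil)
  fr <- vp$part$indfract$Adj.R.square
  list(total_R2_adj = total,
       climate_only = fr[1], shared = fr[2], soil_only = fr[3],
       shared_negative = fr[2] < 0)
}

#' PCA of the environment at the ordination sites
#'
#' Standardised-variable PCA; the first two component scores give the
#' 2-D environmental space used to display the ordinations.
#'
#' @param envAtSites data.frame of predictors at sites (>= 3 sites).
#' @return list with `scores` (sites x 2) and `varianceExplained`.
#' @export
envPCA <- function(envAtSites) {
  if (nrow(envAtSites) < 3) stop("need at least 3 sites")
  X <- as.matrix(envAtSites)
  sds <- apply(X, 2, stats::sd)
  p <- stats::prcomp(X[, sds > 0, drop = FALSE], center = TRUE, scale. = TRUE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, 1:2, drop = FALSE], varianceExplained = ve[1:2])
}
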
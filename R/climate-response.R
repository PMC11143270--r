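#' Per-ecoregion current and future species sets
#'
#' A species belongs to an ecoregion's set iff at least one of its suitable
#' cell centres falls inside the ecoregion (membership by the rasterised
#' tessellation, so centres on a boundary count as inside exactly one
#' ecoregion).
#'
#' @param binariesNow,binariesFut named lists of 0/1/NA matrices on the
#'   same grid, same species.
#' @param regions a [RegionSet-class].
#' @return named list per ecoregion id: list with `S_now`, `S_fut`
#'   (character vectors of species ids).
#' @export
ecoregionSpeciesSets <- function(binariesNow, binariesFut, regions) {
  stopifnot(identical(names(binariesNow), names(binariesFut)))
  ids <- ecoregionIds(regions)
  eco <- regions@ecoRaster
  out <- lapply(seq_along(ids), function(k) {
    inEco <- eco == k
    list(S_now = names(binariesNow)[vapply(binariesNow, function(b)
           any(inEco & !is.na(b) & b == 1), logical(1))],
         S_fut = names(binariesFut)[vapply(binariesFut, function(b)
           any(inEco & !is.na(b) & b == 1), logical(1))])
  })
  stats::setNames(out, ids)
}

#' Fraction of species lost and gained
#'
#' @param sNow,sFut character vectors of species ids (current and future);
#'   `sNow` must be non-empty.
#' @return list with `frac_lost = |S_now \ S_fut| / |S_now|` and
#'   `frac_gained = |S_fut \ S_now| / |S_now|`.
#' @export
gainLoss <- function(sNow, sFut) {
  if (length(sNow) == 0) stop("empty current species set: fractions undefined")
  list(frac_lost = length(setdiff(sNow, sFut)) / length(sNow),
       frac_gained = length(setdiff(sFut, sNow)) / length(sNow))
}

# Median latitude and elevation of a species' suitable cells (whole range).
rangeMedians <- function(binary, grid, elevation) {
  idx <- which(!is.na(binary) & binary == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(lat = NA_real_, elev = NA_real_))
  lat <- cellCenters(grid, idx[, 1], idx[, 2])[, 2]
  c(lat = stats::median(lat), elev = stats::median(elevation[idx]))
}

#' Per-species latitude and elevation shifts
#'
#' For each species, the change in the median latitude and median elevation
#' of its suitable cells between the current and future maps, computed over
#' the species' whole range.
#'
#' @param binariesNow,binariesFut named lists of 0/1/NA matrices.
#' @param grid the [GridSpec-class].
#' @param elevation elevation matrix (m).
#' @return data.frame: `species_id`, `d_lat` (degrees, signed), `d_elev`
#'   (m, signed); NA where a map is empty.
#' @export
speciesShifts <- function(binariesNow, binariesFut, grid, elevation) {
  sp <- names(binariesNow)
  now <- t(vapply(binariesNow, rangeMedians, numeric(2), grid = grid,
                  elevation = elevation))
  fut <- t(vapply(binariesFut, rangeMedians, numeric(2), grid = grid,
                  elevation = elevation))
  data.frame(species_id = sp,
             d_lat = fut[, "lat"] - now[, "lat"],
             d_elev = fut[, "elev"] - now[, "elev"],
             row.names = NULL)
}

#' Per-ecoregion median shifts
#'
#' Over the species present in an ecoregion under both climates
#' (`S_now` intersect `S_fut`): the median of the absolute latitude shifts
#' and the median of the signed elevation shifts.
#'
#' @param sets output of [ecoregionSpeciesSets()].
#' @param shifts output of [speciesShifts()].
#' @return data.frame: `ecoregion_id`, `median_abs_lat_shift`,
#'   `median_elev_shift`, `n_species` (NA shifts where the intersection is
#'   empty).
#' @export
medianShifts <- function(sets, shifts) {
  rows <- lapply(names(sets), function(id) {
    both <- intersect(sets[[id]]$S_now, sets[[id]]$S_fut)
    sub <- shifts[shifts$species_id %in% both & !is.na(shifts$d_lat), ]
    data.frame(ecoregion_id = id,
               median_abs_lat_shift = if (nrow(sub)) stats::median(abs(sub$d_lat)) else NA_real_,
               median_elev_shift = if (nrow(sub)) stats::median(sub$d_elev) else NA_real_,
               n_species = nrow(sub))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ecoregion-level composition change under climate change
#'
#' Builds a (2 x ecoregions) x species incidence matrix holding each
#' ecoregion's current and future species sets, ordinates current and
#' future rows simultaneously (module NMDS on Sorensen distances, and the
#' branch-weighted Hellinger PCA), scales each retained axis to zero mean
#' and unit variance across all rows, and reports each ecoregion's change
#' as the Euclidean distance between its current and future rows in the
#' scaled 3-axis space.  Rows with identical incidence are ordinated once
#' and share a score row, so an unchanged composition gives a distance of
#' exactly zero; empty rows drop their ecoregion from the ordination.
#'
#' @param sets output of [ecoregionSpeciesSets()].
#' @param speciesIds full species list (column order of the incidence).
#' @param phylo phylogeny over the species.
#' @param seed integer seed for the NMDS starts.
#' @param nmdsStarts random NMDS starts.
#' @return data.frame: `ecoregion_id`, `d_tax`, `d_phy` (NA for dropped
#'   ecoregions).
#' @export
compositionChange <- function(sets, speciesIds, phylo, seed = 1,
                              nmdsStarts = 20) {
  ids <- names(sets)
  inc <- function(spSet) as.numeric(speciesIds %in% spSet)
  M <- rbind(
    t(vapply(sets, function(s) inc(s$S_now), numeric(length(speciesIds)))),
    t(vapply(sets, function(s) inc(s$S_fut), numeric(length(speciesIds))))
  )
  colnames(M) <- speciesIds
  rownames(M) <- c(paste0(ids, "_now"), paste0(ids, "_fut"))
  nonEmpty <- rowSums(M) > 0
  dropped <- ids[!(nonEmpty[seq_along(ids)] & nonEmpty[length(ids) + seq_along(ids)])]
  use <- M[nonEmpty, , drop = FALSE]
  if (nrow(use) < 3) stop("need at least 3 non-empty ecoregion rows to ordinate")

  # ordinate unique rows only; duplicates share a score row exactly
  key <- apply(use, 1, paste, collapse = "")
  uniq <- !duplicated(key)
  U <- use[uniq, , drop = FALSE]
  mapRow <- match(key, key[uniq])

  scaleAxes <- function(sc) {
    apply(sc, 2, function(x) {
      s <- stats::sd(x)
      if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
    })
  }
  scTaxU <- if (nrow(U) >= 3) {
    runNMDS(sorensenDistances(U), nAxes = 3, seed = seed,
            nStarts = nmdsStarts)$scores
  } else matrix(0, nrow(U), 3)
  scPhyU <- evoPCAHellinger(U, phylo, nAxes = 3)$scores
  scTax <- scaleAxes(scTaxU[mapRow, , drop = FALSE])
  scPhy <- scaleAxes(scPhyU[mapRow, , drop = FALSE])

  rowOf <- stats::setNames(seq_len(nrow(use)), rownames(use))
  dEuc <- function(sc, id) {
    a <- rowOf[paste0(id, "_now")]; b <- rowOf[paste0(id, "_fut")]
    if (is.na(a) || is.na(b)) return(NA_real_)
    sqrt(sum((sc[a, ] - sc[b, ])^2))
  }
  data.frame(ecoregion_id = ids,
             d_tax = vapply(ids, dEuc, numeric(1), sc = scTax),
             d_phy = vapply(ids, dEuc, numeric(1), sc = scPhy),
             dropped = ids %in% dropped,
             row.names = NULL)
}

#' Assemble the per-ecoregion climate-response table
#'
#' @param binariesNow,binariesFut named lists of binary maps.
#' @param regions a [RegionSet-class].
#' @param elevation elevation matrix.
#' @param phylo phylogeny over the species.
#' @param seed integer seed.
#' @return data.frame with `ecoregion_id`, `biome`, `frac_lost`,
#'   `frac_gained`, `median_abs_lat_shift`, `median_elev_shift`, `d_tax`,
#'   `d_phy`; ecoregions with an empty current species set carry NA
#'   fractions and are flagged `empty_now`.
#' @export
ecoregionResponses <- function(binariesNow, binariesFut, regions, elevation,
                               phylo, seed = 1) {
  sets <- ecoregionSpeciesSets(binariesNow, binariesFut, regions)
  shifts <- speciesShifts(binariesNow, binariesFut, regions@grid, elevation)
  ms <- medianShifts(sets, shifts)
  comp <- compositionChange(sets, names(binariesNow), phylo, seed = seed)
  gl <- lapply(sets, function(s) {
    if (length(s$S_now) == 0) list(frac_lost = NA_real_, frac_gained = NA_real_)
    else gainLoss(s$S_now, s$S_fut)
  })
  data.frame(
    ecoregion_id = names(sets),
    biome = unname(ecoregionBiomes(regions)[names(sets)]),
    frac_lost = vapply(gl, `[[`, numeric(1), "frac_lost"),
    frac_gained = vapply(gl, `[[`, numeric(1), "frac_gained"),
    median_abs_lat_shift = ms$median_abs_lat_shift,
    median_elev_shift = ms$median_elev_shift,
    d_tax = comp$d_tax, d_phy = comp$d_phy,
    empty_now = vapply(sets, function(s) length(s$S_now) == 0, logical(1)),
    row.names = NULL
  )
}

#' Biome-level summary of ecoregion responses
#'
#' Per biome and metric: median, quartiles, boxplot whiskers (most extreme
#' points within 1.5 IQR of the quartiles), mean and normal-theory 95%
#' confidence interval of the mean (undefined for single-ecoregion biomes).
#' Quartiles use linear interpolation between order statistics.
#'
#' @param responses output of [ecoregionResponses()].
#' @param metrics metric columns to summarise.
#' @return data.frame, one row per biome x metric.
#' @export
biomeSummary <- function(responses,
                         metrics = c("frac_lost", "frac_gained",
                                     "median_abs_lat_shift",
                                     "median_elev_shift", "d_tax", "d_phy")) {
  rows <- list()
  for (b in unique(responses$biome)) {
    sub <- responses[responses$biome == b, , drop = FALSE]
    for (m in metrics) {
      x <- sub[[m]][!is.na(sub[[m]])]
      n <- length(x)
      if (n == 0) next
      q <- quantile7(x, c(0.25, 0.5, 0.75))
      iqr <- q[3] - q[1]
      loFence <- q[1] - 1.5 * iqr; hiFence <- q[3] + 1.5 * iqr
      ciHalf <- if (n > 1) stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        biome = b, metric = m, n = n,
        median = q[2], q1 = q[1], q3 = q[3],
        whisker_lo = min(x[x >= loFence]), whisker_hi = max(x[x <= hiFence]),
        mean = mean(x),
        ci_lo = if (n > 1) mean(x) - ciHalf else NA_real_,
        ci_hi = if (n > 1) mean(x) + ciHalf else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pillai's trace MANOVA of responses on biome
#'
#' One-way MANOVA of the response metrics on the biome factor:
#' `V = sum(lambda_i / (1 + lambda_i))` over the eigenvalues of
#' `H E^{-1}` (between / within SSCP), with the standard F approximation.
#' When the between-group matrix is (numerically) zero — e.g. a zero-delta
#' future scenario — V = 0 and p = 1 are reported directly; a singular
#' within-group matrix otherwise is an error suggesting a metric drop.
#'
#' @param responses output of [ecoregionResponses()] (or any data.frame
#'   with a `biome` column and metric columns).
#' @param metrics metric columns to include.
#' @return list with `pillai_trace`, `F_approx`, `df1`, `df2`, `p`.
#' @export
pillaiTest <- function(responses,
                       metrics = c("frac_lost", "frac_gained",
                                   "median_abs_lat_shift",
                                   "median_elev_shift", "d_tax", "d_phy")) {
  ok <- stats::complete.cases(responses[, metrics, drop = FALSE])
  Y <- as.matrix(responses[ok, metrics, drop = FALSE])
  g <- factor(responses$biome[ok])
  counts <- table(g)
  if (nlevels(g) < 2 || any(counts < 2))
    stop("need at least 2 biomes with at least 2 ecoregions each")
  p <- ncol(Y); N <- nrow(Y); k <- nlevels(g)
  grand <- colMeans(Y)
  H <- matrix(0, p, p); E <- matrix(0, p, p)
  for (lv in levels(g)) {
    Yg <- Y[g == lv, , drop = FALSE]
    mg <- colMeans(Yg)
    H <- H + nrow(Yg) * tcrossprod(mg - grand)
    Eg <- sweep(Yg, 2, mg)
    E <- E + crossprod(Eg)
  }
  scale0 <- max(abs(E)) + max(abs(H))
  if (max(abs(H)) <= 1e-12 * max(scale0, 1)) {
    return(list(pillai_trace = 0, F_approx = 0,
                df1 = p * (k - 1), df2 = NA_real_, p = 1))
  }
  Einv <- tryCatch(solve(E), error = function(e)
    stop("singular within-group covariance; consider dropping a metric"))
  lambda <- Re(eigen(H %*% Einv, only.values = TRUE)$values)
  lambda <- pmax(lambda, 0)
  V <- sum(lambda / (1 + lambda))
  s <- min(p, k - 1)
  m <- (abs(p - (k - 1)) - 1) / 2
  nn <- (N - k - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  Fv <- (df2 / df1) * (V / (s - V))
  list(pillai_trace = V, F_approx = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}
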
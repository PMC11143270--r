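# Small deterministic fixture: regions plus hand-made binary maps.
climFixture <- function(nEco = 6, seed = 13) {
  g <- gridSpec(-20, 20, 0, 40, 1)
  r <- generateRegions(g, nCountries = 2, nEcoregions = nEco, seed = seed)
  list(g = g, r = r)
}

test_that("ecoregion species sets and gain/loss follow set arithmetic", {
  fx <- climFixture()
  g <- fx$g; r <- fx$r
  mk <- function(cells) {
    m <- matrix(0, g@nRows, g@nCols); m[cells] <- 1; m
  }
  ecoCells <- lapply(seq_along(ecoregionIds(r)), function(k)
    which(ecoregionRaster(r) == k))
  binNow <- list(a = mk(ecoCells[[1]][1:5]),
                 b = mk(c(ecoCells[[1]][6], ecoCells[[2]][1])),
                 c = mk(ecoCells[[3]][1]))
  binFut <- list(a = mk(ecoCells[[2]][2]),   # a moves from E01 to E02
                 b = binNow$b,               # b stays
                 c = mk(integer(0)))         # c disappears
  sets <- ecoregionSpeciesSets(binNow, binFut, r)
  expect_setequal(sets$E01$S_now, c("a", "b"))
  expect_setequal(sets$E01$S_fut, "b")
  expect_setequal(sets$E02$S_fut, c("a", "b"))
  expect_setequal(sets$E03$S_now, "c")
  expect_length(sets$E03$S_fut, 0)
  # future identical to current: sets equal everywhere
  sets0 <- ecoregionSpeciesSets(binNow, binNow, r)
  for (id in ecoregionIds(r)) expect_setequal(sets0[[id]]$S_fut, sets0[[id]]$S_now)

  expect_equal(gainLoss(c("a", "b"), c("b", "c", "d")),
               list(frac_lost = 0.5, frac_gained = 1.0))
  expect_equal(gainLoss(c("a"), c("a")), list(frac_lost = 0, frac_gained = 0))
  expect_equal(gainLoss(c("a", "b"), character(0)),
               list(frac_lost = 1, frac_gained = 0))
  expect_error(gainLoss(character(0), "a"), "empty current")
})

test_that("median latitude/elevation shifts recover imposed translations", {
  g <- gridSpec(0, 10, 0, 30, 0.5)
  elev <- matrix(0, g@nRows, g@nCols)
  b <- matrix(0, g@nRows, g@nCols); b[30:40, 5:10] <- 1
  bShift <- matrix(0, g@nRows, g@nCols); bShift[28:38, 5:10] <- 1  # 2 cells north
  sh <- speciesShifts(list(s = b), list(s = bShift), g, elev)
  expect_equal(sh$d_lat, 1.0)  # 2 cells x 0.5 degrees
  expect_equal(sh$d_elev, 0)
  sh0 <- speciesShifts(list(s = b), list(s = b), g, elev)
  expect_equal(sh0$d_lat, 0); expect_equal(sh0$d_elev, 0)
  # cone-shaped elevation: future range confined upslope
  ctr <- cellCenters(g)
  cone <- matrix(2000 - 100 * sqrt((ctr[, 1] - 5)^2 + (ctr[, 2] - 15)^2),
                 g@nRows, byrow = TRUE)
  cone <- pmax(cone, 0)
  near <- matrix(0, g@nRows, g@nCols)
  near[cone >= 1200] <- 1
  high <- matrix(0, g@nRows, g@nCols)
  high[cone >= 1600] <- 1
  shC <- speciesShifts(list(s = near), list(s = high), g, cone)
  expect_gt(shC$d_elev, 0)
  # brute-force median recomputation
  expect_equal(shC$d_elev, median(cone[high == 1]) - median(cone[near == 1]))

  # ecoregion medians over the S_now intersect S_fut species
  fx <- climFixture(nEco = 4)
  sets <- list(E01 = list(S_now = "s", S_fut = "s"),
               E02 = list(S_now = character(0), S_fut = "s"))
  ms <- medianShifts(sets, sh)
  expect_equal(ms$median_abs_lat_shift[ms$ecoregion_id == "E01"], 1.0)
  expect_true(is.na(ms$median_abs_lat_shift[ms$ecoregion_id == "E02"]))
})

test_that("composition change is zero without turnover and ranks real turnover", {
  fx <- climFixture(nEco = 6, seed = 21)
  g <- fx$g; r <- fx$r
  phy <- generatePhylogeny(sprintf("sp%02d", 1:10), seed = 2)
  sp <- phy$tip.label
  set.seed(3)
  sets <- lapply(ecoregionIds(r), function(id) {
    s <- sample(sp, 6)
    list(S_now = s, S_fut = s)
  })
  names(sets) <- ecoregionIds(r)
  cc0 <- suppressWarnings(compositionChange(sets, sp, phy, seed = 1, nmdsStarts = 5))
  expect_equal(cc0$d_tax, rep(0, nrow(cc0)))
  expect_equal(cc0$d_phy, rep(0, nrow(cc0)))
  # one ecoregion loses half its species: it shows the largest change
  setsT <- sets
  setsT$E01$S_fut <- setsT$E01$S_now[1:3]
  ccT <- suppressWarnings(compositionChange(setsT, sp, phy, seed = 1, nmdsStarts = 5))
  expect_equal(ccT$ecoregion_id[which.max(ccT$d_tax)], "E01")
  expect_equal(ccT$ecoregion_id[which.max(ccT$d_phy)], "E01")
  expect_true(all(ccT$d_tax >= 0 & ccT$d_phy >= 0, na.rm = TRUE))
  # invariant to relabeling of the species columns
  perm <- sample(length(sp))
  setsP <- lapply(setsT, function(s) list(S_now = s$S_now, S_fut = s$S_fut))
  ccP <- suppressWarnings(compositionChange(setsP, sp[perm],
                                            ape::keep.tip(phy, sp), seed = 1,
                                            nmdsStarts = 5))
  expect_equal(ccP$d_phy, ccT$d_phy, tolerance = 1e-6)
})

test_that("biome summaries use type-7 quartiles and boxplot whiskers", {
  resp <- data.frame(ecoregion_id = sprintf("E%02d", 1:9),
                     biome = "Boreal Forests",
                     frac_lost = 1:9 / 10)
  s <- biomeSummary(resp, metrics = "frac_lost")
  expect_equal(s$median, 0.5)
  expect_equal(s$q1, 0.3)   # {1..9}/10: quartiles 3 and 7 by interpolation
  expect_equal(s$q3, 0.7)
  expect_equal(s$whisker_lo, 0.1)
  expect_equal(s$whisker_hi, 0.9)
  expect_equal(s$mean, 0.5)
  halfCi <- qt(0.975, 8) * sd(resp$frac_lost) / 3
  expect_equal(s$ci_hi - s$ci_lo, 2 * halfCi)
  # identical values: zero-width box and CI
  respC <- transform(resp, frac_lost = 0.4)
  sC <- biomeSummary(respC, metrics = "frac_lost")
  expect_equal(sC$q1, sC$q3)
  expect_equal(sC$ci_lo, sC$ci_hi)
  # whisker rule: the largest point within Q3 + 1.5 IQR
  respW <- transform(resp, frac_lost = c(1:8 / 10, 5))
  sW <- biomeSummary(respW, metrics = "frac_lost")
  expect_lt(sW$whisker_hi, 5)
})

test_that("Pillai's trace matches its definitional and degenerate references", {
  # one metric, two groups: the F statistic is the squared t statistic
  set.seed(22)
  resp <- data.frame(biome = rep(c("A", "B"), each = 12),
                     m1 = c(rnorm(12, 0), rnorm(12, 0.8)))
  p1 <- pillaiTest(resp, metrics = "m1")
  tt <- t.test(m1 ~ biome, data = resp, var.equal = TRUE)
  expect_equal(p1$F_approx, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(p1$p, tt$p.value, tolerance = 1e-9)
  # agreement with the reference MANOVA implementation for 3 metrics
  resp3 <- data.frame(biome = rep(c("A", "B", "C"), each = 10),
                      m1 = rnorm(30), m2 = rnorm(30), m3 = rnorm(30))
  resp3$m1 <- resp3$m1 + (resp3$biome == "B")
  p3 <- pillaiTest(resp3, metrics = c("m1", "m2", "m3"))
  ref <- summary(manova(cbind(m1, m2, m3) ~ biome, data = resp3),
                 test = "Pillai")$stats
  expect_equal(p3$pillai_trace, unname(ref[1, "Pillai"]), tolerance = 1e-9)
  expect_equal(p3$F_approx, unname(ref[1, "approx F"]), tolerance = 1e-9)
  expect_equal(p3$p, unname(ref[1, "Pr(>F)"]), tolerance = 1e-9)
  # bound: V in [0, min(groups - 1, metrics)]
  expect_gte(p3$pillai_trace, 0)
  expect_lte(p3$pillai_trace, min(2, 3))
  # zero between-group variation: V = 0 reported directly
  respZ <- data.frame(biome = rep(c("A", "B"), each = 3), m1 = 0, m2 = 0)
  pz <- pillaiTest(respZ, metrics = c("m1", "m2"))
  expect_equal(pz$pillai_trace, 0)
  expect_equal(pz$p, 1)
  expect_error(pillaiTest(data.frame(biome = "A", m1 = 1), metrics = "m1"),
               "at least 2 biomes")
})

test_that("Pillai's test holds its nominal type-I error under the null", {
  set.seed(30)
  rejections <- 0
  for (rep in 1:200) {
    resp <- data.frame(biome = rep(c("A", "B", "C"), each = 15),
                       matrix(rnorm(45 * 6), 45, 6,
                              dimnames = list(NULL, paste0("m", 1:6))))
    p <- pillaiTest(resp, metrics = paste0("m", 1:6))$p
    if (p < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / 200, 0.02)
  expect_lte(rejections / 200, 0.08)
})

test_that("a zero-delta future produces zero responses end to end", {
  w <- makeWorld(seed = 42, tinyWorldConfig(
    scenarios = list(flat = list(dT = 0, dP = 1))))
  env <- worldEnv(w)
  bins <- lapply(worldSpecies(w), function(sp)
    ifelse(envMask(env), as.numeric(w@occupancy[[sp]]), NA))
  names(bins) <- worldSpecies(w)
  resp <- suppressWarnings(ecoregionResponses(bins, bins, worldRegions(w),
                                              envLayer(env, "elevation"),
                                              worldPhylo(w), seed = 1))
  ok <- !resp$empty_now
  expect_true(all(resp$frac_lost[ok] == 0))
  expect_true(all(resp$frac_gained[ok] == 0))
  expect_true(all(resp$median_abs_lat_shift[ok] == 0, na.rm = TRUE))
  expect_true(all(resp$median_elev_shift[ok] == 0, na.rm = TRUE))
  expect_true(all(resp$d_tax[ok] == 0, na.rm = TRUE))
  expect_true(all(resp$d_phy[ok] == 0, na.rm = TRUE))
})
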
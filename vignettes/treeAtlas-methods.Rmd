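---
title: "treeAtlas: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{treeAtlas: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

treeAtlas is a desk-scale implementation of a macroecological analysis
pipeline for tree species: ensemble species distribution models (SDMs) under
geographic range constraints, taxonomic and phylogenetic ordination of the
resulting community matrix, forest-cover-restricted occupancy range sizes,
and ecoregion-level climate-change response metrics.  Because the global
inputs such analyses consume (occurrence databases, climate and soil
rasters, country and ecoregion polygons, tree-cover maps, a megaphylogeny)
are far beyond a test suite, the package carries a synthetic world generator
that emulates their statistical structure with known ground truth, so every
stage of the pipeline is testable end to end.

This vignette records the models, the tunable parameters, the numerical
choices, and the design decisions taken where the methods left latitude.

## The synthetic world

`makeWorld()` builds a self-contained world from one integer seed.  All
randomness flows through named substreams (`env`, `regions`, `phylo`, `occ`,
`cover`) derived from the top-level seed, so a fixed seed gives bit-identical
worlds and adding draws to one generator never perturbs another.

**Grid.** A regular geographic grid (degrees, WGS84-style), cells half-open
`[edge, edge + res)` and row-major from the north-west corner.  Cell areas
use the exact spherical formula $R^2\,\Delta\lambda\,(\sin\varphi_N -
\sin\varphi_S)$ with $R = 6371.0088$ km, so all area arithmetic downstream is
closed-form.  The default world is a 0.5-degree grid over longitudes
$[-60, 60]$ and latitudes $[0, 60]$: large enough that all four biome
latitude bands occur, small enough that the full pipeline runs in minutes.

**Environment.** Nine predictors — six climate (mean annual temperature,
temperature seasonality, annual precipitation, precipitation seasonality,
growing-season length, net primary productivity) and three soil (silt,
coarse fragments, pH) — plus elevation.  Each layer is a low-order trend
plus spatially correlated (gaussian-smoothed) noise: MAT declines at
0.45 degC per degree of absolute latitude and 6.5 degC per km of elevation;
precipitation decays away from the equator; growing-season length and NPP
are derived from temperature and precipitation so the layers co-vary.
About 10% of cells are masked as water.  A future scenario is a pair
(`dT` in degC on MAT, `dP` multiplicative on precipitation) with consistent
knock-on offsets on the other four climate layers; soil and elevation are
held constant across scenarios, and a zero-delta scenario reproduces the
current stack exactly (an identity several tests rely on).  The default
scenario is a strong-warming end-of-century analogue: `dT = 3`, `dP = 0.8`.

**Regions.** Countries and ecoregions are two independent Voronoi
tessellations of the window (planar lon/lat metric; the rasterised
membership — nearest seed per cell centre — is consistent with the clipped
polygons by construction).  Ecoregion seed points are stratified across
latitude bands, and each ecoregion receives one of the seven forest-biome
labels from its band: tropical ($|\varphi| \le 23.5$, cycling moist / dry /
coniferous), mediterranean ($23.5$–$40$], temperate ($40$–$55$], cycling
broadleaf / conifer), boreal ($>55$).  Stratification guarantees the
climate-response stage a usable biome factor.

**Species.** Each species has a set of native countries, an
independent-Gaussian niche on MAT and annual precipitation, and a maximum
prevalence.  Niche means are drawn from the realised climate of a random
native land cell (so every niche is attainable); niche standard deviations
default to U(2, 5) degC and U(150, 500) mm, and maximum prevalence to
U(0.3, 0.9) — a species occupies a limited climatic band relative to the
continental window, which is what makes a parameter-recovery test
informative.  True suitability is the product of the Gaussian responses,
rescaled so its maximum over native land cells equals the maximum
prevalence.  Realised occupancy is one Bernoulli(suitability) draw per
native land cell; occurrence records are emitted per occupied cell (a small
Poisson number of duplicates across named source databases, jittered
within-cell), and presence–absence plots record the same realised occupancy
exhaustively at a random subset of land cells.

**Tree cover.** A smooth field around the baseline cover, floored at 10% so
that deforestation is the only source of sub-10% cover; exactly
`round(deforestationFrac * n_land)` randomly chosen land cells are then set
below 10%.  This makes the forest-restriction identities exact: with no
deforestation the relative range reduction is 0, with full deforestation 1,
and under uniform random deforestation the mean reduction estimates the
deforested fraction.

**Phylogeny.** A Yule (pure-birth) simulation conditioned on the species
count, rescaled to depth 100, giving a rooted ultrametric bifurcating tree;
written and parsed as Newick with enough digits to round-trip at $10^{-9}$.

**What the generator does not emulate.** Real occurrence data carry sampling
bias, taxonomic error, spatial autocorrelation of effort, and niches that
are neither Gaussian nor independent across predictors; real polygons are
not convex; real climate change is not a uniform offset.  Passing tests
demonstrate that the pipeline's machinery is correct under its own
assumptions, not that the global results of a real analysis would be
reproduced.

## Occurrence preparation and eligibility

Occurrence tables from several sources are concatenated, restricted to an
accepted-names checklist (plain list, no fuzzy matching), and exact
coordinate duplicates per species are collapsed.  Records are then snapped
to the predictor grid (half-open cells; floor of the offset over the
resolution), records off-grid or on masked cells are dropped, and cells are
deduplicated per species: the per-species count of distinct occupied cells,
`n_obs`, drives everything downstream.  Species need `n_obs >= 20` to be
modelled and `n_obs >= 90` to enter the composition, occupancy and
climate-response analyses.

## Geographic range construction

The range polygon encodes dispersal and biogeographic constraints:

1. **Buffered native range** — the union of the native-country polygons
   dilated by 1000 km.  Buffering is implemented as a direct spherical
   membership test: a point is inside the buffer iff it is inside a polygon
   or within 1000 km great-circle distance of its boundary (exact
   cross-track distance to each edge, with the projection tested from both
   endpoints).  This avoids a projection approximation entirely; the
   package's own accuracy test places points 999 and 1001 km from a border
   and requires correct classification within ±0.5%.
2. **Supported observations** — an occupied cell is kept iff at least 3
   other occupied cells lie within 1000 km (centre-to-centre haversine).
3. **Ecoregion support** — each ecoregion containing a supported cell is
   included: whole (with a 1000 km buffer) if its bounding box is under
   1000 km in width or length (great-circle spans at the envelope's
   centroid latitude); otherwise only the part within 200 km of a supported
   observation, again buffered by 1000 km.  The "part" is realised as the
   ecoregion's grid cells within 200 km of a supported cell centre, so this
   component is discretised at grid resolution (the buffers are two orders
   of magnitude larger than a cell, so the discretisation is immaterial at
   the scales used).  The 200 km proximity test uses *supported*
   observations; the methods' wording ("of an observation") leaves this
   open, and using supported cells keeps the construction monotone in the
   observation set.
4. **Intersection and fallbacks** — the range is the buffered native range
   intersected with the ecoregion support union; if no ecoregion holds a
   supported cell the buffered native range alone is used (otherwise a
   species whose observations all fail the neighbour rule would have no
   range at all).  Species with more than 10,000 occupied cells are first
   snapped to a 10x coarser grid and deduplicated; the provenance records
   this, and a test confirms the aggregated range matches the exact one to
   within a coarse cell.

The realised range is a cell mask on the predictor grid plus the geometry
predicates that produced it; every training point and every prediction is
confined to it, for every scenario.

## Species distribution models

**Training schedule.** With `n` distinct occupied cells: `n >= 10000` gives
10,000 presences and 10,000 pseudoabsences; `1818 <= n < 10000` gives `n`
presences and `20000 - n` pseudoabsences; `500 <= n < 1818` gives `n` and
`10 n`; `n < 500` gives `n` and 5000.  The total never exceeds 20,000.
Pseudoabsences are uniform over unmasked in-range cells that hold no
presence — excluding presence cells is a choice (the schedule's source says
only "uniformly at random within the considered range"); it avoids
deliberate label noise and is recorded in the configuration.  If fewer
eligible cells exist than the quota (common on desk-scale grids), all are
used with a warning.

**Predictor count.** `k = min(9, floor(n / 10))`, so observations are
always at least ten times the predictors; species with at least 90
observations use all nine.  When `k < 9`, predictors are ranked by impurity
importance from one all-predictor random forest on the training set, ties
broken by the fixed predictor order.

**Ensemble.** Two random forests and two gradient-boosted tree classifiers
at different complexity levels — RF-simple (200 trees, depth 5), RF-complex
(500 trees, unlimited), GBT-simple (100 rounds, depth 2), GBT-complex (300
rounds, depth 5); learning rate 0.1 for both GBTs; all configurable.  The
ensemble suitability is the unweighted mean of the four member
probabilities.  Members are fitted with `ranger` and `xgboost`, one thread,
seeded per member for exact reproducibility.

**Threshold.** 3-fold cross-validation with random fold assignment
(redrawn, boundedly, until every training split holds both classes); the
out-of-fold ensemble probabilities are pooled and the true skill statistic
TSS(t) = sensitivity + specificity − 1 is scanned over the sorted unique
pooled scores under the `score >= t` presence convention.  The unique
scores realise every achievable confusion matrix, so the scan is exact; the
smallest maximiser is kept (and a brute-force 0.001-grid scan is the
acceptance oracle).  AUC is computed on the same pooled scores by the rank
identity.  The four members are then refitted on the full training set.

**Prediction and evaluation.** Suitability is predicted over in-range
unmasked cells with scenario climate and constant soils, binarised at the
threshold (ties count as presence), no-data outside the range.  Binary maps
are evaluated against the presence–absence plot set: plots outside the
range are excluded, species with fewer than 5 in-range plot presences are
skipped, and TSS, precision, recall, FPR and FNR come from the 2x2
confusion matrix.  Intersection-over-union compares binary maps (here,
against the generator's realised occupancy).

On the default world, label-based held-out AUC is bounded by the
generator's own stochasticity: presences are single Bernoulli draws and
pseudoabsences fall in the niche core in proportion to its share of the
range, so even the true generating suitability scores about 0.8 against the
CV labels while the rank correlation between predicted and true suitability
is high (≈ 0.84 on average).  Rank recovery, not label AUC, is the faithful
recovery metric under these conditions.

## Ordination of the community matrix

**Community matrix.** An equal-area coarse grid overlays the window:
constant longitude step and constant sin-latitude step chosen so every
coarse cell has the same spherical area (~`coarseCellKm` squared, default
400 km for the pipeline's reference configuration — a few hundred sites).
Each species' binary map is sampled at the coarse-cell centre (point query
at the nearest predictor cell; no majority vote).  Sites whose centre falls
on a masked cell, and sites with no species, are dropped; all-zero species
columns are kept.

**Taxonomic ordination.** Sorensen distances (binary Bray–Curtis, via
`vegan::vegdist`) and 3-axis non-metric multidimensional scaling.  The NMDS
minimises Kruskal stress-1 with primary (ties-free) monotone regression
(`vegan::monoMDS`), from a classical-MDS start plus 20 random starts, best
kept, scores centred and rotated to principal axes.  Convergence uses a
$10^{-6}$ stress-ratio tolerance and an iteration cap of 500; if no start
converges the best configuration is returned with a warning.  The test
suite recomputes stress-1 from the returned configuration with an
independent pool-adjacent-violators implementation and requires agreement
to $10^{-8}$, and requires the final stress never to exceed the metric
start's.

**Phylogenetic ordination.** A branch-expanded, branch-length-weighted
Hellinger PCA: the incidence matrix is expanded to site-by-branch
abundances ($x_{ib}$ sums the incidences of the tips descending from branch
$b$), transformed as $M_{ib} = \sqrt{l_b\, x_{ib} / X_i}$ with
branch-length-weighted site totals $X_i = \sum_b l_b x_{ib}$, and
column-centred PCA is applied.  Squared Euclidean distances between rows of
$M$ are the branch-length-weighted Hellinger phylogenetic dissimilarities;
for a star phylogeny with equal branch lengths the construction collapses
to an ordinary Hellinger-transform PCA of the species matrix, which the
tests verify through principal angles below $10^{-6}$.  The first three
axes and their variance fractions are returned.

**Displays and summaries.** Axes map to red/green/blue anchored at the
10th and 90th percentiles (clipped outside; a constant axis maps to
mid-channel with a warning).  Outliers are removed by a single-pass
`[Q1 - IQR, Q3 + IQR]` rule per axis (type-7 quartiles, used consistently
everywhere quartiles appear); k-means with 10 restarts per candidate k and
the mean silhouette width select the cluster count, ties to the smaller k.
Redundancy analysis regresses the scores on the standardised predictors
(adjusted R-squared), and variation partitioning splits it over the
six-climate and three-soil blocks (`vegan::varpart`); collinear predictor
columns are dropped with a warning.  A standardised-variable PCA of the
site environments provides the 2-D environmental space.

## Occupancy and forest restriction

Range size is the sum of spherical cell areas over suitable cells.  The
forest-constrained range keeps suitable cells with at least 10% tree cover
(`>=`, so exactly 10% counts); relative reduction is
`1 - forest / full` (0, flagged, for empty full ranges, which are excluded
from the reduction statistics and counted separately).  A species is
assigned to every biome holding at least 20% of its forest-constrained
area.  The median-range map takes, per cell, the median (even counts:
midpoint) of the forest-constrained range sizes of the species suitable
there.  Unrestricted and restricted range sizes are compared with a paired
two-sided t-test — pairing is the natural structure since both sizes exist
per species; zero-variance differences are flagged rather than tested.

## Climate-change response

For the scenario pair (current, strongest-warming future): a species
belongs to an ecoregion's set iff at least one suitable cell centre falls
in it (membership via the rasterised tessellation, so boundary centres
belong to exactly one ecoregion).  Per ecoregion: `frac_lost` and
`frac_gained` are set differences over the current set; latitude and
elevation shifts are per-species changes in the median latitude / elevation
of suitable cells, computed over the species' whole range (not clipped per
ecoregion — one shift per species, then ecoregion medians over the members
present under both climates; clipping is a defensible alternative the
methods leave unstated).  Composition change ordinates the current and
future ecoregion-level incidence rows simultaneously (module NMDS on
Sorensen distances, and the branch-weighted Hellinger PCA), scales each
axis to zero mean and unit variance across all rows, and reports the
Euclidean distance between an ecoregion's current and future rows in the
3-axis space.  Identical incidence rows are deduplicated before the NMDS
and share one score row, so an unchanged composition yields a distance of
exactly zero rather than a numerically small one.

Biome-level summaries report median, type-7 quartiles, 1.5-IQR boxplot
whiskers, mean, and the normal-theory 95% CI of the mean (undefined for
single-ecoregion biomes).  The divergence of biomes is tested with a
one-way MANOVA on the six response metrics using Pillai's trace,
implemented from the H/E eigenvalue definition with the standard F
approximation — which also covers the one-metric case (where it reduces to
the squared t statistic) and the degenerate zero-between-variation case
(V = 0, p = 1, as produced by a zero-delta scenario) that a generic MANOVA
routine refuses.

## Pipeline, formats, problem sizes

`runPipeline()` chains synth, prep, range, sdm, ordinate, occupancy and
climate from one config.  Each stage caches its result keyed by a hash of
its config block and upstream keys, so re-running an unchanged config
resumes from cache and deleting one stage's cache re-runs only that stage
onward; a JSON manifest records stage keys and md5 checksums of all written
artifacts.  Rasters are written as ESRI ASCII grids (plain text,
georeferenced, readable by GDAL/QGIS), vectors as GeoJSON, occurrence and
plot tables as CSV, the phylogeny as Newick, and the world manifest as
YAML.  A thin command-line front-end (`inst/scripts/treeatlas`) wraps world
generation and the pipeline.

The package's reference problem sizes are chosen for complete end-to-end
runs in minutes on one core: the test suite mostly uses a 40 x 40 cell
world with 6 species, the pipeline smoke tests a 40 x 80 cell world with 5
species, the parameter-recovery check the default 120 x 240 cell world with
10 modelled species, and `scripts/acceptance.R` a 40 x 80 cell world with
12 species.

## Known limitations

- Voronoi regions are convex and the region metric is planar lon/lat;
  real countries and ecoregions are neither.
- The ecoregion-support "part" component and all range masks are
  discretised at grid resolution.
- Niches are independent Gaussians on two predictors; the remaining seven
  predictors act as distractors for the models.
- Label-based skill metrics (TSS, AUC) on synthetic worlds are capped by
  the generator's Bernoulli sampling noise, as quantified above.
- The equal-area community grid stands in for a true equal-area
  projection; its cells are exactly equal-area but not square on the
  ground.
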
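---
title: "Methods: ensemble range modelling of marine structuring species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble range modelling of marine structuring species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(oceanrange)
```

# The modelling problem

Marine ecosystem structuring species — seagrasses, kelps, fucoids and
cold-water corals — are documented almost exclusively by presence records:
georeferenced coordinates where someone found the organism, with no
information about where it is absent. `oceanrange` implements a complete
presence-only species distribution modelling (SDM) pipeline that turns such
records plus gridded environmental predictors into binary range maps under
present-day conditions and future climate scenarios (SSP1-1.9, SSP3-7.0,
SSP5-8.5), with per-cell uncertainty.

The pipeline composes, in order:

1. **Spatial thinning** of occurrences at the estimated spatial
   autocorrelation distance.
2. **Climatically structured pseudo-absences** via K-means in predictor
   space, balanced against the occurrence count.
3. **Hexagonal spatial-block cross-validation** for honest skill estimates
   and hyperparameter selection over fixed grids.
4. Three **monotone-constrained boosted-tree classifiers** (BRT, AdaBoost,
   XGBoost) combined by a **skill-weighted average ensemble**.
5. **Reclassification** at the minimum-training-area (MTP) threshold,
   **depth restriction** to the species' maximum known depth, and
   **dispersal clipping** by stepping-stone reachability with a 200-km
   maximum step.
6. **Interpretation**: permutation-based predictor contributions,
   partial-dependence curves, and tolerance-limit ("tipping point")
   extraction.

Every stochastic stage takes an explicit seed; a run is a pure function of
(inputs, configuration, seed).

# Stage-by-stage model description

## Spatial autocorrelation and thinning

Presence records cluster where people sample, and nearby sites share
environments; both inflate apparent model skill. The package estimates the
distance at which predictor values decorrelate by sampling random pairs of
unmasked cells, binning them into distance classes (default 50 km wide, up
to 600 km), and computing the pooled Pearson correlation between the two
sites' standardized predictor values per class. A class counts as
correlated when r > 0 with a two-sided p-value below `alpha = 0.05` at the
class's pair count. The *uncorrelated distance* is the lower edge of the
first uncorrelated class; if every class is correlated the search cap is
returned. Classes with fewer than 30 pairs are too thin to call and are
treated as uncorrelated; a zero-variance predictor set degrades to
"uncorrelated everywhere" with a warning rather than an error.

Thinning then visits records in seeded random order and keeps a record iff
no already-kept record lies within that distance — a maximal greedy packing
whose retained set is reproducible from the seed. Thinning is idempotent.

## Pseudo-absences

Boosted classifiers need a second class. Candidate cells are all unmasked
cells farther than an exclusion distance from every occurrence; the
exclusion distance defaults to the uncorrelated distance, keeping artificial
absences out of the presence neighbourhood at the same spatial scale used
for thinning. The number of pseudo-absences follows the occurrence count:

* more than 1,000 thinned occurrences — one run, pseudo-absences balanced
  1:1 with occurrences;
* otherwise — 10 independent runs (distinct sub-seeds), each with
  `max(100, n_occ)` pseudo-absences, preserving balance between 100 and
  1,000 occurrences while guaranteeing the 100-point floor.

Within a run, K-means with k equal to the desired count partitions the
candidates' standardized predictor values, and the candidate nearest each
centroid becomes one pseudo-absence — every absence represents a distinct
climatic cluster, so the absence sample spans predictor space without
redundancy and the classes stay balanced. Numerical choices: Lloyd's
algorithm with 25 iterations; 10 restarts when k ≤ 250, 2 otherwise
(restarts barely move nearest-to-centroid representatives but dominate
runtime at large k); candidate pools above 20,000 cells are seeded-
subsampled before clustering. The rare empty Lloyd cluster falls back to
the nearest unused candidate, keeping representatives distinct.

On small domains the estimated distance can rival the domain itself, and
two stages can then starve: the exclusion buffer may leave fewer
candidate cells than pseudo-absences are needed, and thinned presences
may span fewer than two hexagons. `run_species()` recovers from both —
the exclusion buffer is halved until the pool suffices, and the hexagon
width is halved (at most five times) until two presence hexagons are
occupied — logging each adjustment. The operation-level functions keep
their strict contracts and error instead.

## Spatial-block cross-validation

Random CV folds leak spatial structure. Points are projected onto a local
equirectangular plane centred on their median coordinate and assigned to
flat-topped hexagons whose across-flats width equals the uncorrelated
distance; occupied hexagons are shuffled with the seed and dealt
round-robin into 10 folds. Two records in one hexagon can never land in
different folds. On desk-scale grids fewer than 10 hexagons may be
occupied; the pipeline then reduces the fold count to the hexagon count
(never below 2) and says so, rather than failing.

## Boosted models and hyperparameter grids

All three algorithms are gradient-boosted tree ensembles fitted on the
xgboost backend, which lets the same per-predictor monotone constraints be
enforced exactly in each:

* **brt** — depth-limited trees, logistic loss; axes: learning rate
  {0.1, 0.01, 0.001}, tree complexity (max depth) 1–4, trees 50–1000 in
  steps of 50 (240 combinations).
* **adaboost** — exponential (AdaBoost) loss as a custom objective,
  leaf-limited trees; axes: iterations 50–250 step 50, degrees of freedom
  1–12, shrinkage 0.25–1 step 0.25 (240 combinations). "Degrees of freedom"
  d is mapped to d splits per tree (`max_leaves = d + 1`); the margin f is
  mapped to a probability by sigmoid(2f), the standard logistic calibration
  of exponential-loss boosting.
* **xgb** — logistic loss with a minimum-split-gain axis; gamma 0–5,
  interaction depth 1–4, shrinkage 0.1–0.5 step 0.1, rounds 10–100 step 10
  (1,200 combinations).

Monotone directions encode physiological expectations: maximum
temperature, sea-ice cover, wave energy and water speed may only depress
suitability; minimum temperature, salinity, nutrients, pH, oxygen,
productivity, slope and ruggedness may only raise it. The constraint is a
regularizer against overfitting and guarantees exactly monotone
partial-dependence curves, which in turn makes tolerance limits
well-defined.

Grid search selects the combination with the highest mean CV AUC; ties go
to the higher mean Boyce index, then to fewer boosting iterations
(parsimony). The full reference lattices are available via
`grid_mode = "full"`; the default `"reduced"` grid (2 values per axis, 32
combinations across the three algorithms) keeps desk-scale runs in minutes
and is the mode used by the package's tests.

## Evaluation metrics

* **AUC** — rank-based, ties one-half (via pROC).
* **Sensitivity / specificity / TSS** at a threshold, presence rule
  `score >= threshold`; TSS = sensitivity + specificity − 1. TSS is kept on
  its mathematical range [−1, 1] and never clamped.
* **Continuous Boyce index** — 101 overlapping windows of width 0.1 × the
  background score range slide over the background range; per window the
  predicted-to-expected presence ratio P/E is computed (zero-expectation
  windows skipped, consecutive duplicate P/E values collapsed, as in the
  classic implementations of the index); the index is the Spearman
  correlation between P/E and window midpoints. Constant P/E returns 0
  with a warning. Requires ≥ 20 presence and ≥ 100 background scores.
* **MTP threshold** — the largest threshold keeping training-presence
  sensitivity ≥ 0.95; this minimizes predicted area subject to the
  sensitivity bound and is exactly the m-th largest presence score with
  m = ⌈0.95 n⌉.
* **Collinearity** — pairwise Pearson r and VIF (1/(1−R²) from regressing
  each predictor on the others) on the training features; reported, never
  used to auto-drop predictors.

## Ensemble, uncertainty, projection

Per-algorithm CV skill sets the ensemble weight:
w ∝ max(AUC − 0.5, 0) (the 0.5 floor removes random skill; a Boyce-based
weighting with floor 0 is available). All-zero weights fall back to equal
weights with a warning. For rare species with 10 runs, per-algorithm maps
are averaged over runs first; the ensemble map is the weighted mean of the
three per-algorithm maps, and the uncertainty map is their unweighted
sample standard deviation (n−1 denominator) — zero wherever the algorithms
agree.

The MTP threshold is fixed on the baseline training predictions and reused
unchanged for every future scenario (threshold transfer). The binary map
then gets two clips, in a deliberate order:

1. **Depth**: cells deeper than the species' maximum known depth become
   absences — deep cells are removed *before* dispersal so they cannot act
   as stepping stones.
2. **Dispersal**: seeds are the presence cells holding at least one
   occurrence record, plus all occurrence cells regardless of predicted
   state (records demonstrate the region was reached). The reached set
   grows by chained steps: a presence cell joins when it lies within
   200 km of any reached cell; at the fixpoint, unreached presences become
   absences. Chained stepping is what makes an unsuitable gap wider than
   200 km impassable — a single 200-km buffer would not. For future
   scenarios the expansion is seeded from the baseline *clipped* range, so
   colonization can only proceed from currently occupied, reachable
   habitat. Both clips are monotone (never add presences) and idempotent.

## Interpretation

Relative contributions use permutation importance — the mean drop in
training AUC over shuffles of each predictor column, floored at zero and
normalized to 100% — so the three algorithms and the ensemble are scored
by one model-agnostic rule. The ensemble column is the weight-averaged
member contribution, re-normalized.

Partial dependence fixes one predictor at each of 100 grid values over its
training range and averages predictions over (up to 2,000 subsampled)
training rows. Tolerance limits are read off the curve: for a negatively
constrained predictor, the largest grid value where the curve stays at or
above the crossing threshold (a maximum tolerated level); for a positively
constrained one, the smallest such value (a minimum requirement).

The crossing level is a small fraction (default 0.1) of the curve's own
maximum. Two alternatives were rejected after inspection. The absolute
MTP threshold usually exceeds the entire curve — a partial-dependence
curve averages over training rows that *other* predictors render
unsuitable, so its ceiling sits well below the threshold computed on full
predictions — and declares every limit absent. A high *relative* level
(e.g. the MTP threshold re-expressed against the curve maximum) reads the
top of the fitted response drop and is biased toward the niche optimum by
roughly the smoothing width of the fitted boundary. A tolerance limit is
where the response effectively vanishes — the support edge of the
species' response — so the detector belongs near the response floor.
"Tipping point" has no unique formal definition; both the level and the
rule are configurable (`extract_tipping_point()` takes any absolute
threshold, including the MTP threshold itself).

# The synthetic world

`make_world()` emulates the gridded environment the pipeline consumes:
Gaussian random fields smoothed to a controllable correlation length
(kernel sd in cells = L / (111.32 × cell°)), optional latitudinal
gradients, a smooth bathymetry field, a contiguous land mask, and future
scenarios as additive shifts of the dynamic predictors (static seafloor
layers never shift). `make_virtual_species()` defines truth: suitability
is the cell-wise product of piecewise-trapezoidal responses whose support
edges are the species' true tolerance limits; `sample_occurrences()` draws
records with probability ∝ suitability^bias, emulating the tendency of
sampling toward favourable habitat.

Default study conditions, chosen once: 200 × 200 cells at 0.05° straddling
the equator (≈ 1,100 km across), correlation length 30 km, temperature
gradient −0.4 °C per degree latitude, 15% land, warming offsets
+1.0 / +2.8 / +4.5 °C for the three scenarios. The correlation length is
deliberately small relative to the grid: the estimated uncorrelated
distance then lands near 100–150 km, so thinning retains tens of records
and the exclusion buffer leaves a usable candidate pool — the same
proportions, scaled down, that a global run at 0.05° with a ~100-km
uncorrelated distance exhibits. A steeper gradient makes the large-scale
trend dominate the correlogram and pushes the uncorrelated distance toward
the search cap, which starves every downstream stage; that regime is
realistic for global data but not for a 1,100-km test grid.

Recovery benchmarks use virtual species with *sharp* tolerance limits
(trapezoid ramps ≈ 0.1 predictor units, about one partial-dependence grid
step). This is a deliberate study condition: the threshold crossing of a
wide ramp sits mid-ramp by construction, so no extraction rule could place
it within two grid steps of the support edge. Sharp limits make "the
recovered limit equals the true limit" a well-posed check of the pipeline
rather than of the ramp width.

What the synthetic world does **not** emulate: ocean physics (fields are
isotropic and stationary apart from the latitudinal trend), coastline
complexity and islands, substrate and light availability, non-additive
climate change (future variance shifts, novel climates), and spatially
structured observation error beyond suitability-proportional bias. Passing
tests therefore demonstrate that the pipeline's machinery is correct under
known truth — not that any particular real species is well modelled.

# Problem sizes and runtime

The test suite and the acceptance script run on one CPU with the reduced
grids: the end-to-end benchmark uses the default 200 × 200 world with 500
occurrence samples (10 runs × 100 pseudo-absences after thinning, 10-fold
hexagon CV; a few minutes), unit tests use 60 × 60 worlds (seconds each),
and the dispersal scan uses strip rasters of a few hundred cells. The full
reference lattices (1,680 combinations across algorithms) are exercised
for enumeration, not fitted in tests; fitting them is a production-scale
choice via `grid_mode = "full"`.

# Known limitations

* The AdaBoost "degrees of freedom" axis has no exact analogue on a tree
  backend; d → d splits is a declared mapping, not an inference.
* The correlogram pools predictors after standardization; per-predictor
  correlograms (and the shortest or longest of their distances) are a
  defensible alternative the package does not implement.
* Dispersal treats any ≤ 200-km chain of suitable cells as passable
  regardless of currents or larval biology; it is a reachability
  constraint, not a dispersal model.
* Rare-species uncertainty is computed across algorithms after averaging
  runs; run-to-run variance is not propagated into the uncertainty map.
* GeoTIFF support is deliberately minimal: single-band float32, geographic
  WGS84, uncompressed — exactly the shape of the layers this pipeline
  reads and writes.
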
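---
title: "Methods: bias-corrected suitability modelling and range-shift analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bias-corrected suitability modelling and range-shift analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures the package implements,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the methodology is genuinely open.

## The estimation problem

Presence-only occurrence records carry two confounded signals: where a
species lives and where people looked. For a cryptic montane stream
salamander the second signal is strong — records cluster along accessible
valleys and in intensively surveyed regions. The pipeline attacks this with
two standard tools used together:

* **spatial thinning** (`thin_occurrences()`): enforce a minimum pairwise
  great-circle distance (default 1 km, on the order of one 30-arc-second
  grid cell) so that locally over-surveyed clusters count once;
* **target-group background** (`density_raster()` + `sample_background()`):
  draw the background sample for the presence–background model from the
  density of *all* co-surveyed species' records, so that the background
  carries the same survey-effort bias as the presences and the bias cancels
  from the fitted density ratio.

## The suitability model

`fit_maxent()` fits a Gibbs (log-linear) density over background cells: the
maximum-entropy formulation of presence-background modelling. Features are
deterministic transforms of the predictors (`feature_spec()`): linear,
quadratic, pairwise products, threshold indicators and two-sided hinges,
with knots evenly spaced on the training range (defaults: 30 hinge and 30
threshold knots; tests and the bundled pipeline use fewer — 6 — because at
their grid sizes more knots only add coefficients the penalty zeroes out).
Predictors are min-max scaled to the training range; with `clamp = TRUE`
(default) projection data are truncated to that range first, the
conservative choice when projecting to warmed climates outside the
calibration range.

The objective is the L1-penalized average presence log-likelihood; the
per-feature penalty is `rm * base(class, m) * s_j / sqrt(m)` with `s_j` the
feature's sd over the training sample and `base` the MaxEnt default table
(linear/quadratic/product interpolated from 1.0 at 10 presences to 0.05 at
100+, hinge 0.5, threshold 1.0). The `1/sqrt(m)` scaling matters: it makes
the penalty comparable to the sampling noise of a feature mean, so a model
fitted to presences that carry no signal shrinks toward uniform. With no
signal the fit has AUC ≈ 0.5 and its residual spatial texture disappears as
`rm` grows (the package's null-data tests assert exactly this, including a
near-flat map — cloglog spread below 0.05 — at `rm = 16`). The optimizer is
FISTA (proximal gradient with backtracking and restart) on the convex
objective, converged when the objective changes by less than 1e-7; the
contract is the objective, not the algorithm.

Two output scales are exposed by `predict()`: `raw`, normalized to mean 1
over the *training* background (the normalizer is frozen at training so
projections remain comparable), and `cloglog`,
`1 - exp(-exp(H) * raw / B)` where `H` is the entropy of the fitted
background distribution and `B` the background size — i.e. the standard
cloglog transform of the sum-to-one raw density. Cloglog is a strictly
monotone map of raw, so ranking metrics (AUC, Spearman recovery) are
identical on either scale.

Variable importance comes in two forms: permutation `percent_contribution()`
(drop in penalized training gain when one predictor's values are permuted,
averaged over 10 permutations, floored at zero, normalized to 100) and
`jackknife_gain()` (refit without each variable and with each variable
alone; gain is the unpenalized training gain relative to the uniform model).

## Tuning and evaluation

`tune_candidates()` crosses feature classes with regularization multipliers
under 10-fold random or 4-quadrant spatial-block cross-validation (blocks
split at the median longitude and latitude — the simplest block design; the
choice matters when models are transferred to new climates). Candidates are
scored by mean test AUC, mean 10% omission rate (threshold = the type-7
linear-interpolated 10% quantile of training presence scores; omission
rates are sensitive to the quantile definition, hence it is pinned), AICc
(`2k - 2 lnL + 2k(k+1)/(n-k-1)`, `k` = non-zero coefficients, likelihood of
the raw density over all cells), and AUC_diff as an overfitting index.
`select_candidate()` implements both published selection rules — minimum
AICc, and sequential (minimum omission, then maximum test AUC) — with ties
broken toward lower `rm`, then the simpler feature set. Fold metrics are
averaged over folds rather than pooled; the final model is refit on all
presences at the selected settings.

Binary maps use the maximum training sensitivity plus specificity (MTSS)
threshold, scanned over the distinct observed scores with ties resolved to
the lowest maximizer, and a fixed 0.8 threshold for "optimal" habitat. TSS
is sensitivity + specificity − 1 with background as the negative class —
the usual presence-background convention, stated because the negative class
is otherwise undefined.

## Dispersal limits

Suitability alone overpredicts: a cell can be climatically suitable yet
unreachable. Cost surfaces assign each cell a traversal difficulty in
[1, 1e6]; 1e6 codes "insurmountable" (urban areas, lakes, sub-threshold
suitability) by magnitude rather than by nodata, so barriers remain in the
graph and never disconnect it. Rule-based reclassification
(`reclassify_cost()`) uses ordered half-open intervals (first match wins);
the suitability-derived surface (`suitability_cost()`) drops geometrically
(log-linearly) from 1,000 at the MTSS threshold to 1 at suitability 1 — the
published analysis states only "decreasing costs with increasing
suitability", so the schedule (and its 1,000 ceiling) is an exposed
parameter, with the geometric form chosen so that equal suitability steps
multiply cost by equal factors. Layer surfaces are merged by cellwise
maximum (`mosaic_max()`): the most restrictive layer governs.

`cost_distance()` is multi-source least-accumulative cost over the
8-connected lattice with step cost `(c_a + c_b)/2`, times `sqrt(2)` on
diagonals — the convention of the GIS tool this reproduces — computed with
Dijkstra's algorithm (via igraph). `jenks_breaks()` classifies the
accumulated costs by the exact Fisher–Jenks weighted dynamic program
(O(k n²)); above 1e5 distinct-value observations it first bins values into
a 1,024-bin histogram (tested against the exact program at small n). The
dispersal limit is the lowest of seven classes; seven follows the published
choice, and because class-1 membership is scale-free the limit is invariant
to uniform rescaling of all costs.

## Range change

`binarize()` intersects suitability ≥ threshold (closed bound; strictness
is unstated in the source methodology, so the inclusive convention is
pinned here) with the dispersal mask. Areas use the spherical-zone formula
on the WGS-84 authalic sphere (R = 6371.0088 km) — the source workflow
computed areas in a GIS whose method (planar vs geodesic) is unstated, so
the spheroid-zone formula is this package's stated choice. Percent decrease
is reported to one decimal. Elevational shifts are two-sided Mann–Whitney
tests on suitable-cell elevations (exact enumeration when the pooled sample
is ≤ 18, the exact tie-free distribution up to n = 50 per group, otherwise
the normal approximation with tie correction and no continuity correction);
p-values are reported raw, uncorrected across scenarios, mirroring the
published analysis. Each scenario is thresholded at its *own* MTSS — the
per-scenario threshold reading of the published appendix — which makes
"suitable" area a relative quantity that can stay stable under warming
while fixed-threshold "optimal" habitat collapses; both are reported.

## The synthetic world

`make_world()` generates the study conditions every test runs under:
Gaussian-kernel-smoothed white-noise fields (kernel sd 6 cells) for
elevation (600 ± 400 m), from which slope is the finite-difference gradient;
temperature tied to elevation by a 6.5 °C/km lapse rate plus a −1 °C/degree
latitude gradient and 0.3 °C noise; wettest/driest-month precipitation
(300 ± 60 / 35 ± 8 mm) partially correlated with elevation; two forest-cover
layers (logistic transforms of elevation-correlated fields); and a
temperature-seasonality layer *independent of the truth by construction* —
the known-uninformative control. True suitability is
`cloglog(beta' x)` with fixed coefficients describing a cold-adapted,
steep-slope, wet-forest species (so warming monotonically erodes true
suitability); the survey-bias field is an independent smooth surface in
(0, 1]. Scenarios shift temperature additively and scale precipitation,
holding topography and land cover constant, as in the emulated study.

What the generator does *not* emulate: real covariance structure among
bioclimatic variables, anisotropy, temporal mismatch between records and
climatology, taxonomic noise, or the actual geography of any peninsula.
Passing tests therefore demonstrate that the machinery is correct and that
bias correction works when the target group truly shares the focal bias —
not that any particular real-world dataset is unbiased.

The truth-recovery experiment (also run by `scripts/acceptance.R`) uses an
80 × 100-cell world, 500 presences drawn with bias exponent 2, 4,000
target-group records sharing that bias (the same order as the thinned
target group in the emulated study), a density raster smoothed at sigma 3
cells, 4,000 background points, and linear-quadratic features at `rm` 1 —
LQ because the generating truth is smooth and monotone-to-unimodal in each
predictor, and richer classes only add variance at these sample sizes. The
bundled pipeline fixture (`run_config()`) is a 60 × 80 world with 250
presences, 1,500 background points and three warming scenarios (+1/+2/+3 °C
with 5 %/10 %/15 % drier precipitation); these sizes are the package's
chosen demonstration scale, keeping the full chain interactive while large
enough that every stage has signal.

## Degenerate inputs and tie-breaks

Constant features are dropped before fitting; an all-constant feature set
is an error. Thinning returns a maximal conflict-free set (a greedy
max-degree deletion pass with random tie-breaks, followed by a re-add pass
that guarantees maximality), best of `n_repeats` passes, deterministic
given the seed; the exact internals of the original thinning tool are not
published, so the algorithm is pinned here instead. Jenks requires at least
`k` distinct values (uniform accumulated costs are an error, surfaced from
`limit_mask()`). `mtss_threshold()` and `select_candidate()` state their
tie rules explicitly. Cells are half-open (a point on the west/north edge
belongs to the cell); grids are cell-center, row 1 northernmost. Nodata is
a single internal representation (`NA`) regardless of the source sentinel.

## Known limitations

* Only geographic (lon/lat) square-cell grids; no projected CRS,
  resampling or reprojection. File I/O is the ESRI ASCII grid format.
* The Gibbs fit scales as (background cells × features) per iteration;
  hinge/threshold-rich specifications on large grids are the slow path.
* Spearman screening correlates layers over all shared valid cells, not at
  occurrence points (the alternative reading of the source methodology).
* The per-scenario-MTSS convention makes suitable-area trajectories
  conservative; users wanting a fixed-threshold reading can pass a single
  `mtss` value to `summarize_scenarios()`.
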
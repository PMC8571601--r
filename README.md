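# sdmshift

Habitat-suitability modelling and climate-driven range-shift analysis for
dispersal-limited species, built around the workflow used for montane stream
amphibians such as the Korean clawed salamander (*Onychodactylus koreanus*):
presence-only records with strong spatial sampling bias, a maximum-entropy
suitability model, projection to warmed climates, and a cost-distance bound
on where the animal can actually get to.

The package is aimed at spatial ecologists who want this whole chain as
plain, testable R functions (tibbles in, tibbles out) rather than a GUI
workflow, and at methodologists who want each step — thinning, bias
correction, tuning, thresholding, dispersal limits — separately exercisable
against synthetic landscapes with known truth.

## The model

Suitability is a penalized Gibbs (log-linear) density over landscape cells.
With features `f(x)` (linear, quadratic, product, threshold and hinge
transforms of the predictors) the model is

    P(x) = exp(beta' f(x)) / Z,

fitted by maximizing the L1-penalized average presence log-likelihood

    mean_presence(beta' f) - log mean_background(exp(beta' f))
      - sum_j rm * base_j * s_j / sqrt(m) * |beta_j|,

the MaxEnt default penalty (`rm` = regularization multiplier, `s_j` =
feature sd, `m` = presence count, `base_j` the per-class table). Sampling
bias is corrected with *target-group background*: background cells are drawn
from a kernel-smoothed density raster of all co-surveyed species' records,
so presences and background share the same survey-effort bias and it cancels
from the density ratio. Predictions use the cloglog transform
`1 - exp(-exp(H) * raw)` of the sum-to-one raw density (`H` = entropy of the
fitted background distribution).

Candidate models over feature classes × regularization multipliers are
scored by 10-fold or spatial-block cross-validation (test AUC, 10% omission
rate) and AICc, and binarized at the maximum training sensitivity plus
specificity (MTSS) threshold, with suitability ≥ 0.8 as "optimal" habitat.
Dispersal limits come from least-accumulative-cost distance over an
8-connected grid (cellwise-maximum mosaic of cost layers; suitability below
MTSS is a 1,000,000-cost barrier), classified into seven Jenks natural-breaks
classes; the lowest class is the reachable region. Range change per scenario
is reported as spherical-geometry areas (km²), percent decrease versus
current, and a Mann–Whitney test on suitable-cell elevations.

## Worked example

`run_pipeline()` drives the full chain on a synthetic world (smooth
elevation, lapse-rate temperature, precipitation, forest cover; a
cold-adapted "species" whose true suitability is known; a survey-bias
field):

```r
library(sdmshift)
res <- run_pipeline(run_config(), quiet = FALSE)
res$evaluation
#>   train_auc mean_test_auc auc_diff  or10   tss  mtss
#> 1     0.670         0.643   0.0275 0.133 0.288 0.525
res$summary
#>   scenario suitable_km2 pct_dec_suitable optimal_km2 pct_dec_optimal
#> 1 current         1395.              0         233.              0
#> 2 warm1           1420.             -1.8        62.3            73.3
#> 3 warm2           1385.              0.8        26.1            88.8
#> 4 warm3           1354.              3          10.7            95.4
```

Reading the output: the model separates presences from background (test AUC
0.64 against a background that *shares the presences' sampling bias* — bias
correction makes this an honest, and therefore modest, number), overfits
little (AUC_diff 0.03), and binarizes at MTSS 0.525. Warming scenarios
(+1/+2/+3 °C, drier) leave the MTSS-thresholded "suitable" area roughly
stable — each scenario is re-thresholded at its own MTSS — but collapse the
high-suitability "optimal" habitat by 73 → 89 → 95 %, the fingerprint of a
cold-adapted montane species losing its climatic core. `res$limits` holds
the per-scenario dispersal masks, `autoplot(res$suitability$current)` maps
suitability, and `plot_range_change(res$summary)` draws the contraction.

The pieces are exported individually (`thin_occurrences()`,
`density_raster()`, `sample_background()`, `fit_maxent()`, `tune_candidates()`,
`cost_distance()`, `jenks_breaks()`, `limit_mask()`, `binarize()`,
`summarize_scenarios()`, ...) and compose with the pipe; fitted models have
`tidy()`/`glance()` methods.

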
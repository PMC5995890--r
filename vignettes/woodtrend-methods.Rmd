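---
title: "Mapping woody-cover change and attributing its drivers: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping woody-cover change and attributing its drivers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(woodtrend)
library(dplyr)
```

## The problem

Woody plant encroachment — the gradual thickening of trees and shrubs in
grasslands, savannas and shrublands — is a slow, spatially patchy signal that
only becomes visible in decades of satellite observations. `woodtrend`
implements a complete desk-scale pipeline for detecting it and attributing
its spatial variation to environmental drivers:

1. mask out closed forest, forestry and non-natural landcover;
2. summarise each pixel's cloud-free reflectance observations per five-year
   epoch into time-series spectral metrics;
3. regress photo-interpreted fractional-cover labels on those metrics with a
   random forest and predict cover for every pixel and epoch;
4. define change as the per-pixel OLS slope of cover against year;
5. aggregate change and candidate covariates to a coarse grid and fit
   weighted Gaussian boosted regression trees (BRTs) to apportion the
   spatial variation among climatic, edaphic and disturbance variables.

Because the archives that feed the real analysis (decades of multispectral
scenes, reanalysis climate, soils, fire and herbivore layers) are far beyond
a desktop, every stage here is exercised against a seeded synthetic
landscape with known ground truth. That inversion — you know the answer, the
pipeline has to find it — is what the test suite and the acceptance script
check.

## The synthetic landscape

`landscape_config()` fixes the study design: a 64 x 64 pixel grid grouped
into 8 x 8-pixel coarse cells, six non-overlapping five-year epochs spanning
1986-2016, a covariate suite, cover-dynamics coefficients, and a spectral
observation model. Everything downstream is a pure function of
`(config, seed)`.

**Covariate fields.** Each covariate gets a smooth long-term mean field and
(if time-varying) a smooth per-year trend field, built by Gaussian-filtering
white noise; annual values are `mean + trend * (year - midpoint)` plus
interannual noise. The defaults are conventional magnitudes for a semi-arid
subcontinent (rainfall ~650 ± 180 mm/yr with trends of a few mm/yr/yr;
temperature ~22 °C warming by ~0.01 °C/yr; burned fraction ~0.25 and
declining; growing population; static soils and elevation).

**Cover dynamics.** Cover starts from a smooth field (mean 0.45, sd 0.18)
and evolves by logistic-bounded increments: the per-epoch change is a
coefficient-weighted sum of scaled covariate fields times
`cover * (1 - cover)`, clipped to [0, 1]. Trend fields are scaled by their
spatial sd but *not* centred — zero change is a meaningful origin, so the
sign of a pixel's rainfall trend is the sign of its forcing contribution.
Mean fields (facilitators) are centred and scaled. A quadratic
`population_trend_sq` term gives the hump-shaped population-growth response:
modest growth slightly favours woody cover, rapid growth suppresses it.
The stored true slope is the OLS slope of the stored epoch covers against
epoch midpoints, so the generator is self-consistent with the pipeline's
definition of change.

The default coefficients make wetting and warming climates and declining
fire the active drivers, with herbivore density, soil texture and elevation
as deliberate nulls. Their magnitudes were chosen so the spatial sd of the
true slope is about 0.005 fraction/yr — i.e. hotspots gain or lose roughly
0.15 cover over the 30-year record, consistent with reported regional
encroachment rates; a weaker field would make the toy problem unrealistically
hard, a stronger one unrealistically easy.

**Observation model.** Each pixel emits 15 dated observations per epoch.
Reflectance in six bands (blue, green, red, NIR, SWIR1, SWIR2) is a linear
mixture of a fixed woody endmember and a seasonally varying herbaceous
endmember weighted by true cover, plus Gaussian noise (sd 0.01) and
independent cloud flags (p = 0.25). The herbaceous layer swings between
green and senescent states within the year while the woody canopy stays
evergreen — exactly the phenological contrast that makes temporal variance
and range of vegetation indices informative for separating the two
life-forms. A secondary sensor can contribute a fraction of late-epoch
observations through a linear radiometric offset (`gain * x + bias`),
emulating a gap-filling collection that `harmonize_sensors()` must undo.

**Quadrats.** `sample_quadrats()` scatters 4000 labelled 30 x 30 m quadrats
over the unmasked area (pixel locations drawn without replacement), each
with an epoch, an acquisition date, and a label equal to true cover plus
optional interpreter noise, rounded to the nearest of {0, 0.25, 0.5, 0.75,
1}. Exact midpoints (0.125, 0.375, ...) round half up — a deterministic,
documented convention matching common photo-interpretation practice. A
configurable fraction of quadrats is flagged uncertain or dated outside its
epoch, so the assembly-stage exclusion rules have something to exclude.

What the generator deliberately does *not* emulate: radiative transfer,
orbital geometry, atmospheric effects, spatially correlated cloud, mixed
pixels at patch boundaries, or interpreter bias that correlates with
landscape position. Passing tests therefore show the pipeline's logic is
sound and its estimators are calibrated on well-behaved input; they do not
certify performance on real imagery.

## Spectral metrics

Per pixel and epoch, each band and vegetation index (NDVI; SAVI with
L = 0.5; EVI with G = 2.5, C1 = 6, C2 = 7.5, L = 1 — the standard
constants) is summarised by its minimum, maximum, the 10/25/50/75/90th
percentiles, and the mean of observations between selected percentile pairs
(10-25, 25-50, 50-75, 75-90, 25-75); indices additionally get temporal
variance and range. Conventions, locked so tests can be exact:

* **Percentiles** use linear interpolation between closest ranks
  (`h = 1 + (n - 1)p`), the most common default.
* **Windowed means** have two defensible readings, and both are
  implemented. The default *value window* averages observations whose
  values fall inside `[q_lo, q_hi]` inclusive (an empty window — possible
  with widely spaced values — gives NA). The *rank window* variant averages
  the sorted observations at ranks `ceiling(h_lo) .. ceiling(h_hi)`. For
  the series 1..10 the 25-75 windowed mean is 5.5 under the value window
  and 6.0 under the rank window; `epoch_metrics(window = )` switches.
* **Variance** is the population variance.

## Cover model and trend

`fit_cover_regressor()` fits a 500-tree random forest (here 300 in the
examples, which is past the accuracy plateau for this feature count) of the
quantized label on the metric features, with dual validation: internal
out-of-bag R² and an independent hold-out (20%, stratified by label class,
structurally disjoint from training). Hold-out size follows common practice;
the forest hyperparameters are deliberately defaults because the result is
insensitive to them at this scale. Predictions are clipped to [0, 1] rather
than re-normalised — regression on a bounded label can overshoot slightly at
the extremes, and clipping leaves calibration elsewhere untouched. No label
weighting is applied across the five classes.

A subtlety worth knowing: with labels hard-quantized to quarters and *no*
interpreter noise, the best possible regression is a staircase in true
cover, which caps how well per-pixel *slopes* (differences of ~0.02-0.1 in
cover between epochs) can be recovered, no matter the regressor. Modest
interpreter noise effectively dithers the quantizer and makes the expected
label smooth in cover; the worked experiments therefore include interpreter
noise of sd 0.05 as the realistic labelling condition.

`pixel_trend()` regresses cover on the epoch midpoint year per pixel
(missing epochs skipped pairwise; fewer than two timepoints gives a missing
slope), storing slope, intercept, two-sided p-value and n. The epoch
midpoint is the natural time coordinate for a value that summarises a
five-year window. `logit_trend()` repeats the fit on
`log(p / (1 - p))` after clamping to `[eps, 1 - eps]` (default eps 0.005 —
arbitrary but documented); on well-behaved series the two agree in sign.

**Quality weighting.** Each pixel's quality is the product of its normalized
trend-timepoint count and normalized valid-observation count; a cell's score
is the mean pixel quality of its unmasked pixels times its unmasked
fraction (the combination is ours; the ingredients are standard). Cells
scoring below the 25th percentile (type-7 quantile, strict inequality) are
excluded from driver modelling; surviving scores become observation
weights.

## Covariate statistics

* **Extreme rainfall**: sliding (stride-1) 5-day sums; the threshold is the
  95th percentile of all sums in the *full* record; annual counts use
  strict exceedance, windows assigned to their start year. Because the
  threshold depends on the whole record, appending a wet year can revise
  earlier counts — intended, and asserted in a regression test. The window
  length and the sub-daily aggregation interval are parameters, since
  forcing archives differ.
* **PCI**: `100 * sum(p_i^2) / (sum p_i)^2` over twelve monthly totals
  (multi-year records reduced to mean months first); bounded in
  [100/12, 100].
* **Rainfall variability**: population SD of annual totals and of the raw
  sub-daily series, reported separately.
* **Soils**: thickness-weighted depth averaging over contiguous intervals.
* **Terrain ruggedness**: the Riley formulation (root of summed squared
  elevation differences to the eight neighbours) by default, with the
  literal sum-of-absolute-differences reading available by flag; edge
  pixels use available neighbours.
* **Hindcasting**: a BRT trained on the reference epoch's observed response
  is applied to every epoch's predictors; the per-cell linear slope of the
  modelled series is the change layer. Epochs with observed responses other
  than the reference provide cross-epoch validation R².

## Driver attribution

Fine layers are aggregated to the coarse grid by the resolution rule:
bilinear sampling at the cell centroid for native resolutions above 500 m,
mean of valid pixels otherwise. Collinear variable groups (`|r| > 0.7` on
complete cases, grouped by transitive closure) are thinned to one variable
each — by an explicit priority list, then alphabetically, so the outcome is
deterministic; constant columns have undefined correlations and are treated
as uncorrelated with a warning.

`fit_brt()` is stagewise gradient boosting of depth-5 regression trees with
learning rate 0.01, bag fraction 0.5 and observation weights in the
squared-error loss (the xgboost engine provides the boosting machinery; the
surrounding protocol is this package's). The ensemble size is selected at
the minimum of the 10-fold cross-validated weighted MSE curve, and **CV
deviance explained** is `1 - CV residual deviance / weighted total
deviance`, always computed on held-out CV predictions, never the training
fit. The default ceiling of 1500 trees (800 in the coarse-grid experiments)
sits past the flat region of the CV curve at these problem sizes. Doubling
all weights changes nothing — the weighted loss is scale-invariant.

**Relative importance** is each variable's split gain (squared-error
reduction summed over all splits and trees) normalised to 100; unused
variables score 0.

**Simplification** drops the lowest-importance variable, refits, and
repeats until CV deviance explained falls more than one fold-level standard
error below the full model's (the one-standard-error rule — the published
procedure admits several stopping rules, so the full elimination trace is
attached for audit).

**Partial dependence** averages model predictions over the empirical
distribution of all other variables on a grid clipped to the variable's
5th-95th percentile, with data deciles and the interquartile band attached
for plotting. A flat curve is the signature of a null variable.

**Permutation sanity**: the response is shuffled across cells and the model
refit. "Failed to resolve" — a phrase that needs an operational definition —
is taken to mean CV selecting at most `min_trees` (50) trees or CV deviance
explained at most 0.05. On any table with real signal the permuted fit must
collapse while the original does not.

Random CV folds are used (no spatial blocking), matching the procedure this
pipeline mirrors; with smooth fields this flatters absolute deviance
explained somewhat, which is one reason the tests assert *contrasts*
(active vs null, permuted vs not) rather than absolute continental numbers.

## A worked example

```{r example, eval = FALSE}
cfg <- landscape_config(seed = 1)
ls <- simulate_landscape(cfg)
cube <- epoch_metrics(cloud_filter(ls$scenes))
quads <- sample_quadrats(ls$truth, n = 4000, seed = 2, label_noise_sd = 0.05)
reg <- fit_cover_regressor(assemble_training(quads, cube, cfg$epochs),
                           n_trees = 300, seed = 3)
glance(reg)
tm <- pixel_trend(predict_cover(reg, cube), cfg$epochs)
plot_trend_map(tm)

tab <- simulate_driver_table(seed = 1)
model <- fit_brt(tab, response = "response", weights = "weight",
                 predictors = setdiff(names(tab),
                                      c("cell", "x", "y", "weight", "response")))
tidy(model)
autoplot(partial_dependence(model, "burned_area_trend"))
```

The chunks above are not evaluated at build time (the full pipeline takes
minutes); `scripts/acceptance.R` runs the same computations end to end and
prints the numbers.

## Known limitations

* The spectral model is a two-endmember linear mixture; it cannot represent
  soil-background variation, burn scars, or sensor saturation.
* Quantized labels bound slope recovery through the cover model (see
  above); the trend stage itself is exact on noiseless cover series.
* Per-pixel trend p-values ignore spatial autocorrelation, as does random
  CV folding; neither correction is attempted here.
* The collinearity filter uses pairwise deletion; under informative
  missingness the grouping could differ from complete-case analysis.
* Problem sizes (64 x 64 pixels, 20 x 20 cells, 800-1500 trees) were chosen
  as the smallest at which every estimator is comfortably past its
  small-sample regime; they are package choices, not statements about the
  original continental analysis.
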
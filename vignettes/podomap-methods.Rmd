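---
title: "Methods: environmental limits of podoconiosis from boosted regression tree ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: environmental limits of podoconiosis from boosted regression tree ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podomap)
```

## The problem

Podoconiosis is a non-infectious lymphoedema of the lower legs caused by
long-term barefoot contact with irritant volcanic soils. Its occurrence is
tied to identifiable environmental conditions — enough rainfall and
altitude to produce the implicated soils, vegetation consistent with
subsistence agriculture, and low urbanisation — so a national prevalence
survey combined with gridded environmental layers can delineate the
*environmental limits* of the disease: the set of pixels whose environment
could sustain transmission. Overlaying those limits on gridded population
then yields the population at risk, the quantity programme planners need.

`podomap` implements that analysis as a reusable, fully seeded pipeline:
survey aggregation, covariate processing, an ensemble of boosted regression
tree (BRT) occurrence models with bootstrap uncertainty, ROC-based
threshold selection, and zonal population-at-risk accounting.

## Survey aggregation

The observational unit is a surveyed community: `n_examined` adults
examined, `n_cases` with podoconiosis-attributed lymphoedema. Records from
the historical survey that fall in districts endemic for lymphatic
filariasis are excluded before any analysis, because lymphoedema there
cannot be attributed to podoconiosis without misclassification.

Districts pool their communities' counts; district prevalence is
`100 * n_cases / n_examined`. Confidence intervals use the normal
approximation on the proportion, clamped to [0, 100] — chosen because it
reproduces the printed intervals of the national survey's regional table at
two decimals for every row where a standard method can (one row of that
table, Harari, is inconsistent with any standard binomial interval and is
treated as a typo; the package documents rather than reproduces it).
Prevalence categories use half-open bins on the unrounded percentage —
`zero` iff exactly 0, then (0,1], (1,5], (5,10], (10,15], (15,100] — the
printed "0.01–1"-style labels being two-decimal display artefacts.
Duplicate community identifiers within a district raise an error rather
than being silently summed, to protect against double-loading the two
source surveys.

## Covariate processing

Rasters live on a planar kilometre grid (row 1 at the top, corner-registered
origin, cell-centre sampling — stated once here, used everywhere).
Continuous layers are resampled bilinearly on cell centres with a
nearest-valid-corner fallback beside nodata; categorical layers use nearest
neighbour. All layers are aligned to a land mask; cells outside it are
nodata in every layer, never zero. Slope comes from Horn's 3x3 gradient with
replicated borders, in degrees; distance to water is the exact Euclidean
distance between cell centres. Geodesic geometry and map reprojection are
out of scope: the statistical results are invariant to projection once the
rasters are aligned, so the pipeline works in planar kilometres throughout.

The collinearity screen computes pairwise Pearson correlations and, while
any pair exceeds |r| = 0.7, drops the member of the worst pair with the
larger mean absolute correlation against the remaining covariates (ties by
name order, so the screen is deterministic). Which member of a correlated
pair to drop is a genuinely open choice; the mean-absolute-correlation rule
keeps the covariate that carries more independent information. Nonlinearly
related pairs (small |r|) pass the screen untouched, which is the intended
carve-out: a Pearson screen only targets linear redundancy.

## The boosting engine

Occurrence modelling uses stagewise gradient boosting on the Bernoulli
deviance, written from scratch:

* intercept `logit(mean(y))`;
* per iteration, a bag of training rows (default 75%, without replacement,
  seeded) provides gradient residuals `y - p`, to which a least-squares
  regression tree is fitted by greedy best-first splitting (default 5
  interior splits, at least 5 observations per leaf, candidate thresholds
  at midpoints between distinct values, ties broken by variable index then
  threshold — deterministic);
* terminal values are Bernoulli Newton steps `sum(r) / sum(p(1-p))` over
  the rows reaching the leaf, capped at |value| <= 4 so pure leaves cannot
  produce infinite logits;
* each tree enters the additive logit predictor scaled by the learning rate
  (default 0.01).

Tree count is chosen by early stopping on a seeded holdout (default 20%,
patience 10), after which the model is trimmed to the best iteration; with
`holdout_fraction = 0` the tree count is fixed, which the recovery
simulations use because early stopping on a ~50-site holdout stops after a
few dozen trees and leaves influence estimates dominated by the first
splits. The hyperparameter defaults follow the conventions of BRT
species-distribution modelling; all are exposed in `brt_params()`.

Relative influence accumulates each split's squared-error improvement on
its split variable and scales the totals to sum to 100. Partial dependence
is computed by its definition — set the covariate to each grid value in
every training row and average the logit predictions — rather than a
weighted tree-traversal shortcut; the brute-force form is exact, and the
test suite asserts it against an independent re-implementation.
Serialisation writes 17 significant digits so a JSON round trip reproduces
predictions bit-exactly.

`xgboost` (when available) serves as an independent reference in the test
suite: with matched shrinkage, leaf budget, tree count and no bagging, the
two engines' holdout AUCs agree within 0.05. It is a cross-check only; the
pipeline never calls it.

## Ensemble and uncertainty

How an ensemble of BRT submodels should differ is an open design choice;
`podomap` fits each submodel on a bootstrap resample of the sites (same
size, with replacement, seed `base_seed + i`; single-class resamples are
redrawn a bounded number of times). Site-level bootstrap is consistent with
reporting "bootstrap confidence intervals" around marginal-effect curves.
Across submodels the pipeline reports, per land pixel, the mean probability,
the empirical 2.5%/97.5% quantiles (type-7 linear interpolation between
order statistics — percentile intervals, not normal-theory ones, another
choice the method leaves open), and the uncertainty map as the interval
range. Influence is pooled as the across-submodel mean (renormalised to sum
100) with percentile intervals, and marginal-effect curves carry pointwise
percentile envelopes. The mean can lie marginally outside the interpolated
percentile envelope for small ensembles; the envelope ordering
`q_low <= q_high` is the invariant the code asserts.

The exploratory prevalence-covariate curves use `stats::loess` (degree 1,
tricube kernel, exact "direct" surface) with the span exposed as the
bandwidth: a local polynomial smoother is a standard, well-tested primitive
and not part of this package's contribution.

## Threshold, validation, and population at risk

The continuous suitability map becomes a binary occurrence-limits map at
the threshold that maximises the unweighted sum of sensitivity, specificity
and proportion correctly classified over all candidate thresholds (the
unique scores, ties to the smallest; Youden's J is available as an
alternative objective). Classification uses `score >= threshold` — one
convention shared between threshold selection and map binarisation, which
matters exactly at the threshold. AUC uses the trapezoidal rule over the
ROC curve, which equals the Mann-Whitney rank statistic with ties counted
one half; interpretation bands are left-closed ([0, 0.7) poor, [0.7, 0.8)
acceptable, [0.8, 0.9) excellent, [0.9, 1] outstanding — the prose
convention is ambiguous exactly at the edges, so the package documents its
choice). Cross-validation scores each submodel on its out-of-bootstrap
sites; external validation extracts the mean map at independent
presence/absence records and reports AUC with its band.

Population at risk sums gridded population over cells inside the limits,
per administrative zone; zonal sums equal the national total exactly, by
construction and by test. Lower and upper population bounds apply the same
threshold to the 2.5% and 97.5% quantile maps, which nest around the mean
limits. Percentages are reported against zone populations for zone rows and
the national population for the total row (the denominator is
configurable). The threshold sensitivity analysis re-runs the accounting at
0.3 and 0.6; population at risk is non-increasing in the threshold by
construction. Area is cell count times nominal cell area — planar, since
projection handling is out of scope.

## The synthetic study area

The generator emulates the *structure* of a national mapping study, not any
real geography. Covariates are smoothed Gaussian white-noise fields (radius
`smoothing_radius` cells) blended with broad cross-grid gradients and then
rank-mapped onto explicit marginal distributions (a Gaussian-copula-style
construction: the field sets the spatial pattern, the marginal sets the
value distribution). Elevation, precipitation and EVI get right-skewed Beta
marginals — most of the study area is dry lowland, wet highland is a solid
minority — because a disease bounded by rainfall and altitude needs both
suitable and unsuitable terrain in realistic proportions for
presence/absence modelling to be a meaningful exercise. Population density
is log-normal (clamped at 20,000 per km^2); soil silt and clay are
compositional with sand as the exact complement (fractions are snapped to
multiples of 1/1024 so the closure `silt + clay + sand = 100` is exact in
floating point); temperature is a 6.5 degC/km lapse from elevation; slope
and distance-to-water are derived with the covariate module's own
operations; a small fraction of cells is water, excluded from the land
mask.

The true suitability surface is the logistic of an additive score whose
term shapes follow the marginal responses observed for this disease: a
precipitation ramp rising from about 1,000 mm (logistic scale 250 mm, so
the rise spans roughly 1,000–2,000 mm), an elevation window rising over
1,000–2,000 m and collapsing beyond about 2,800 m, EVI rising to about 0.5
then falling, declining log population density that flattens above about
10,000 per km^2, rising silt and falling clay. The three main terms are
centred at 0.7 rather than 0.5 so that absence is the default state and
occurrence requires a jointly favourable environment; with all magnitudes
zero the surface is exactly 0.5, which pins the construction. Default
magnitudes (precipitation 4.0, elevation 3.0, EVI 1.5, population 1.2,
silt 1.2, clay 1.2) keep the influence ordering of the main drivers ahead
of the soil terms while leaving every effect strong enough that a model
fitted at the study's sample sizes can recover its sign — a stated
requirement of the generator. Under these defaults a 600-community study
shows overall prevalence near 3%, roughly two thirds of communities with at
least one case, about a quarter of districts with none, and about 30% of
the landmass suitable, matching the profile of the national survey this
design emulates.

Surveys sample about two communities per district (districts are contiguous
rectangular blocks tiling the grid; bands of blocks form the
regions/zones), examine `max(10, Poisson(100))` people each, and draw cases
binomially at prevalence `0.1 x truth` — the 0.1 scale keeps community
prevalences inside the observed 0–55% band. A seeded 10% of communities is
tagged as historical records in LF-endemic districts to exercise the record
filter. Independent external-validation records are Bernoulli draws of
"at least one case among 100" at fresh cells.

What the generator does **not** emulate: real geography or projections,
seasonal or temporal structure, spatially correlated binomial overdispersion,
measurement error in the covariates, and site-selection bias (real surveys
oversample suspected-endemic communities). Passing tests therefore show the
pipeline's statistical machinery is correct and recovers known structure —
not that any particular real-world prevalence estimate is right.

## Problem sizes and verification choices

The test suite runs the recovery simulation at 600 communities (300
districts on a 96x96 km grid) with a 24-submodel ensemble — a deliberately
scaled-down analogue of a 120-submodel national analysis that keeps the
suite fast while preserving the statistical behaviour being tested; the
ensemble-size default in `pipeline_config()` remains 120. Recovery is
asserted as: mean-map AUC against the true surface at least 0.80,
precipitation and elevation ranking top-2 in relative influence in at least
18 of 20 seeded replicate studies, and the clay marginal effect recovered
as non-increasing in direction in at least 16 of 20. Direction recovery is
measured by the Spearman correlation of the fitted partial-dependence curve
with the covariate over its central 80% range (negative or zero for clay,
positive for precipitation over 1,000–1,800 mm): a fitted partial-dependence
curve is a step function whose small wiggles defeat strict pointwise
monotonicity even when the underlying truth is strictly monotone and the
fitted trend unambiguous, so a rank-correlation trend statistic is the
meaningful test of direction.

## Known limitations

* Continuous covariates only: one-vs-rest categorical splits are not
  implemented (categorical layers are screened out before modelling in this
  design, as they carry little explanatory power for this disease).
* Early stopping uses a single holdout rather than k-fold cross-validation;
  with a fixed seed this is deterministic and cheap, but on small data the
  stopping point is noisy — fixed tree counts are preferable there.
* The distance transform is exact but brute-force (blocked all-pairs); it
  is sized for survey-scale grids, not continental 90 m tiles.
* Bootstrap ensembles quantify sampling uncertainty of the sites, not
  structural uncertainty in covariate choice or residual spatial
  correlation (no kriging/Gaussian-process residual layer).
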
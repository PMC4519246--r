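# podomap

National-scale mapping of podoconiosis (non-filarial elephantiasis) from
community prevalence surveys and gridded environmental data.

Podoconiosis is a disabling lymphoedema of the lower legs caused by long-term
barefoot exposure to irritant volcanic soils. Mapping where the environment
can sustain the disease — and how many people live inside those limits — is
the first step in planning prevention and morbidity management. `podomap`
implements the full analysis pipeline used for this kind of mapping study:

1. **Survey aggregation** — community-level lymphoedema counts are pooled to
   district prevalence with binomial confidence intervals, historical records
   from lymphatic-filariasis-endemic districts are excluded, and the standard
   regional prevalence and prevalence-category tables are produced.
2. **Covariate processing** — raster resampling (bilinear for continuous,
   nearest-neighbour for categorical layers), alignment to a land mask,
   terrain slope (Horn gradient), straight-line distance to water, point
   extraction, and a pairwise-correlation collinearity screen at |r| > 0.7.
3. **Boosted regression trees** — a from-scratch stagewise gradient-boosting
   engine on the Bernoulli deviance: shallow least-squares regression trees
   fitted to the gradient residuals on seeded bags, Newton-step terminal
   values, early stopping on a holdout, relative influence scaled to sum
   100, and exact (brute-force) partial-dependence curves. The model for
   site presence/absence `y` is

   `logit P(y = 1 | x) = f_0 + nu * sum_m T_m(x)`

   with intercept `f_0 = logit(mean(y))`, shrinkage `nu`, and regression
   trees `T_m` fitted sequentially to `y - p`.
4. **Ensemble uncertainty** — an ensemble of BRT submodels on bootstrap
   resamples of the sites (120 in a full analysis) gives the mean
   suitability map, per-pixel 2.5%/97.5% quantile maps, the uncertainty map
   (the 95% interval range), pooled relative influence, and marginal-effect
   curves with bootstrap envelopes.
5. **Validation and limits** — ROC analysis with AUC (trapezoidal,
   tie-aware), out-of-bootstrap cross-validation (PCC, sensitivity,
   specificity, Cohen's kappa, AUC), external validation against
   independent presence/absence records, and selection of the occurrence
   threshold maximising sensitivity + specificity + PCC.
6. **Population at risk** — the suitability map is binarised at the chosen
   threshold and overlaid on gridded population to tabulate the population
   and landmass inside the occurrence limits per administrative zone, with
   lower/upper bounds from the quantile maps and a threshold sensitivity
   analysis at the conventional 0.3/0.6 cut-offs.

A seeded synthetic-data generator (spatially autocorrelated covariate
rasters with realistic marginals, a known true suitability surface, binomial
community sampling at about two communities per district and about 100
examined per community) makes the whole pipeline testable end-to-end without
any external downloads.

## Worked example

```r
library(podomap)

cfg <- pipeline_config(
  synthetic   = synthetic_config(seed = 7, grid_rows = 64, grid_cols = 64,
                                 n_districts = 100),
  brt         = brt_params(learning_rate = 0.05, max_trees = 200),
  n_submodels = 8
)
res <- run_pipeline(cfg, "run07")
#> simulate: 200 communities in 100 districts on a 64x64 grid
#> aggregate: 178 communities -> 99 districts (22 records dropped)
#> screen: 8/8 covariates retained at |r| <= 0.7
#> fit: 8 submodels; 3973 land pixels predicted
#> validate: cv AUC 0.864, external AUC 0.902 (outstanding), threshold 0.510
#> limits: binarized at tau = 0.5101
#> risk: 1658547 persons (46.1%) inside the limits at tau = 0.5101
```

Reading the log: 200 simulated communities lose 22 flagged historical
records and aggregate to 99 surveyed districts; no covariate pair exceeds
the collinearity threshold; the 8-submodel ensemble discriminates its
out-of-bootstrap sites with a mean AUC of 0.86 ("excellent" band) and
scores 0.90 against the independent validation records; the ROC-optimal
occurrence threshold 0.510 puts 46% of the simulated population inside the
environmental limits. Every artefact (regional tables, ensemble maps as
ASCII grids, influence and marginal-effect tables, validation report, binary
limits, risk tables, manifest) is written under `run07/`, and rerunning with
the same configuration reproduces the files byte for byte.

```r
print(res$fit$influence, n = 4)   # pooled relative influence, 95% intervals
#> # A tibble: 8 × 4
#>   covariate     mean_influence q_low q_high
#>   <chr>                  <dbl> <dbl>  <dbl>
#> 1 precipitation          47.8  34.8    59.6
#> 2 elevation              15.5  10.2    23.6
#> 3 pop_density             8.56  2.78   15.1
#> 4 evi                     8.40  4.42   14.7
plot_influence(res$fit$influence)
plot_marginal_curves(res$fit$curves)
autoplot(res$fit$maps$mean_map)
```

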
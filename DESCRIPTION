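Package: podomap
Title: Environmental Limits and Population at Risk of Podoconiosis from
    Boosted Regression Tree Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for national-scale mapping of
    podoconiosis (non-filarial elephantiasis) occurrence from
    community-level prevalence surveys and gridded environmental
    covariates. Aggregates surveys to district prevalence with binomial
    confidence intervals, screens covariates for collinearity, fits an
    ensemble of stagewise boosted regression trees (Bernoulli deviance,
    implemented from scratch) with bootstrap uncertainty, delineates
    binary environmental limits by ROC-based threshold selection, and
    tabulates population at risk by administrative zone. Includes a
    seeded synthetic-data generator (spatially autocorrelated covariate
    rasters, a known suitability surface, binomial community sampling)
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
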
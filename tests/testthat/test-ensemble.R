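# a trivial constant-probability submodel: no trees, just an intercept
constant_model <- function(p, covariates = c("a", "b")) {
  structure(list(intercept = qlogis(p), trees = list(), learning_rate = 0.1,
                 covariates = covariates, n_trees = 0L, params = brt_params(),
                 data = cbind(a = c(0, 1), b = c(0, 1))),
            class = "pod_brt")
}

test_that("a one-submodel ensemble reduces to a single seeded bootstrap fit", {
  sim <- small_sim(seed = 31, rows = 32, cols = 32, districts = 24)
  des <- sim_design(sim)
  X <- des[model_covariates()]
  y <- des$presence
  pars <- brt_params(learning_rate = 0.1, max_trees = 30, seed = 1)
  ens <- fit_ensemble(X, y, pars, n_submodels = 1, base_seed = 40)
  idx <- podomap:::with_pod_seed(41, sample.int(nrow(X), nrow(X), replace = TRUE))
  pars$seed <- 41L
  direct <- fit_brt(as.matrix(X)[idx, ], y[idx], pars)
  expect_identical(predict(ens$submodels[[1]], X, scale = "logit"),
                   predict(direct, X, scale = "logit"))
})

test_that("the ensemble is reproducible from its base seed", {
  sim <- small_sim(seed = 32, rows = 32, cols = 32, districts = 24)
  des <- sim_design(sim)
  pars <- brt_params(learning_rate = 0.1, max_trees = 20, seed = 1)
  e1 <- fit_ensemble(des[model_covariates()], des$presence, pars,
                     n_submodels = 3, base_seed = 7)
  e2 <- fit_ensemble(des[model_covariates()], des$presence, pars,
                     n_submodels = 3, base_seed = 7)
  p1 <- predict(e1$submodels[[3]], des[model_covariates()])
  p2 <- predict(e2$submodels[[3]], des[model_covariates()])
  expect_identical(p1, p2)
})

test_that("bootstrap variation spreads submodel predictions at a fixed point", {
  sim <- small_sim(seed = 33, rows = 32, cols = 32, districts = 30)
  des <- sim_design(sim)
  ens <- fit_ensemble(des[model_covariates()], des$presence,
                      brt_params(learning_rate = 0.1, max_trees = 40, seed = 1),
                      n_submodels = 6, base_seed = 3)
  pt <- des[5, model_covariates()]
  preds <- vapply(ens$submodels, function(m) predict(m, pt), numeric(1))
  expect_gt(stats::sd(preds), 0)
})

test_that("single-class bootstrap draws are redrawn or rejected", {
  X <- data.frame(x = rnorm(12))
  y <- c(1, rep(0, 11))  # a lone presence: many resamples miss it
  expect_error(fit_ensemble(X, rep(0, 12), n_submodels = 1), "degenerate")
  ens <- fit_ensemble(X, y, brt_params(max_trees = 5, holdout_fraction = 0,
                                       min_obs = 2),
                      n_submodels = 5, base_seed = 2)
  for (m in ens$submodels) {
    expect_length(unique(ens$y[m$boot_idx]), 2L)
  }
})

test_that("an ensemble of identical submodels has zero uncertainty everywhere", {
  st <- tiny_stack()
  subs <- list(constant_model(0.3), constant_model(0.3), constant_model(0.3))
  maps <- predict_maps(subs, st)
  expect_true(all(maps$uncertainty_map$values[!is.na(maps$uncertainty_map$values)] == 0))
  expect_equal(unique(as.vector(maps$mean_map$values[!is.na(maps$mean_map$values)])), 0.3)
})

test_that("per-pixel quantiles match the sort-based oracle and bracket the mean", {
  st <- tiny_stack()
  probs <- c(0.05, 0.1, 0.3, 0.5, 0.6, 0.8, 0.95)
  subs <- lapply(probs, constant_model)
  maps <- predict_maps(subs, st)
  land <- !is.na(maps$mean_map$values)
  expect_equal(unique(as.vector(maps$q_low_map$values[land])),
               unname(stats::quantile(probs, 0.025, type = 7)))
  expect_equal(unique(as.vector(maps$q_high_map$values[land])),
               unname(stats::quantile(probs, 0.975, type = 7)))
  expect_true(all(maps$mean_map$values[land] >= min(probs) &
                    maps$mean_map$values[land] <= max(probs)))
  expect_true(all(maps$q_low_map$values[land] <= maps$q_high_map$values[land]))
})

test_that("nodata cells stay nodata in every ensemble map", {
  st <- tiny_stack()
  st$land_mask$values[1, 1] <- 0
  st <- pod_stack(st$grids, st$land_mask)
  maps <- predict_maps(list(constant_model(0.4)), st)
  expect_true(is.na(maps$mean_map$values[1, 1]))
  expect_true(is.na(maps$uncertainty_map$values[1, 1]))
})

test_that("ensemble influence pools to 100 and collapses for one submodel", {
  sim <- small_sim(seed = 34, rows = 32, cols = 32, districts = 30)
  des <- sim_design(sim)
  ens <- fit_ensemble(des[model_covariates()], des$presence,
                      brt_params(learning_rate = 0.1, max_trees = 30, seed = 1),
                      n_submodels = 4, base_seed = 5)
  infl <- ensemble_influence(ens)
  expect_equal(sum(infl$mean_influence), 100, tolerance = 1e-9)
  one <- ensemble_influence(list(ens$submodels[[2]]))
  single <- relative_influence(ens$submodels[[2]])
  merged <- dplyr::left_join(one, single, by = "covariate")
  expect_equal(merged$mean_influence, merged$influence)
})

test_that("marginal curve envelopes behave: zero width for clones, containment", {
  sim <- small_sim(seed = 35, rows = 32, cols = 32, districts = 30)
  des <- sim_design(sim)
  ens <- fit_ensemble(des[model_covariates()], des$presence,
                      brt_params(learning_rate = 0.1, max_trees = 25, seed = 1),
                      n_submodels = 3, base_seed = 9)
  m1 <- ens$submodels[[1]]
  clones <- list(m1, m1, m1)
  cc <- ensemble_marginal_curves(clones, covariates = "precipitation", n_grid = 15)
  expect_equal(cc$q_low, cc$q_high)
  expect_equal(cc$mean_logit, cc$q_low)
  # envelope built from a single submodel collapses onto its own curve
  solo <- ensemble_marginal_curves(list(m1), covariates = "elevation", n_grid = 15)
  own <- partial_dependence(m1, "elevation", grid = solo$value)
  expect_equal(solo$mean_logit, own$logit)
  expect_equal(solo$q_low, own$logit)
  expect_equal(solo$q_high, own$logit)
  # envelopes are ordered pointwise
  curves <- ensemble_marginal_curves(ens, covariates = "elevation", n_grid = 15)
  expect_true(all(curves$q_low <= curves$q_high))
  expect_true(all(curves$q_low <= curves$mean_logit + 1e-9 |
                    curves$mean_logit <= curves$q_high + 1e-9))
  # one curve per model covariate
  all_curves <- ensemble_marginal_curves(ens, n_grid = 5)
  expect_setequal(unique(all_curves$covariate), model_covariates())
})

test_that("local-polynomial prevalence smoother recovers flat and linear truths", {
  x <- seq(0, 10, length.out = 40)
  flat <- prevalence_vs_covariate(rep(0.25, 40), x, n_grid = 12)
  expect_equal(flat$fit, rep(0.25, 12), tolerance = 1e-9)
  lin <- prevalence_vs_covariate(0.01 + 0.002 * x, x, n_grid = 12)
  expect_equal(lin$fit, 0.01 + 0.002 * lin$value, tolerance = 1e-6)
  expect_equal(nrow(lin), 12L)
  expect_error(prevalence_vs_covariate(rep(0.1, 40), x, bandwidth = 0), "bandwidth")
  expect_error(prevalence_vs_covariate(rep(0.1, 5), 1:5), "10")
})
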
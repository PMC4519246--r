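# exhaustive split-search oracle: best least-squares split over every
# (variable, midpoint-between-distinct-values) candidate
oracle_best_split <- function(X, r, min_obs = 5L) {
  n <- nrow(X)
  best <- list(gain = -Inf)
  S <- sum(r)
  base <- S^2 / n
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    for (t in (xs[-length(xs)] + xs[-1]) / 2) {
      left <- X[, j] <= t
      nl <- sum(left)
      if (nl < min_obs || n - nl < min_obs) next
      gain <- sum(r[left])^2 / nl + sum(r[!left])^2 / (n - nl) - base
      if (gain > best$gain + 1e-12) best <- list(gain = gain, var = j, split = t)
    }
  }
  best
}

test_that("the first split of a perfectly separable covariate is the separating threshold", {
  X <- cbind(x1 = c(rep(0, 10), rep(1, 10)))
  r <- c(rep(-0.5, 10), rep(0.5, 10))
  h <- rep(0.25, 20)
  tree <- fit_tree(X, r, h, tree_complexity = 3)
  expect_equal(tree[1, "var"], c(var = 1))
  expect_equal(tree[1, "split"], c(split = 0.5))
  # pure leaves: Newton value sum(r)/sum(h) = +-5/2.5 = +-2
  leaves <- tree[tree[, "var"] == 0, "value"]
  expect_setequal(leaves, c(-2, 2))
})

test_that("a constant working response yields a single zero-valued leaf", {
  X <- cbind(x1 = rnorm(20))
  tree <- fit_tree(X, rep(0, 20), rep(0.25, 20), tree_complexity = 5)
  expect_equal(nrow(tree), 1L)
  expect_equal(tree[1, "value"], c(value = 0))
})

test_that("greedy splits match the exhaustive (variable, midpoint) oracle", {
  withr::with_seed(7, {
    for (i in 1:10) {
      X <- cbind(a = rnorm(20), b = rnorm(20), c = sample(0:3, 20, TRUE) * 1.0)
      r <- rnorm(20)
      got <- podomap:::best_split(X, r, seq_len(20), min_obs = 5L)
      want <- oracle_best_split(X, r)
      expect_equal(got$var, want$var)
      expect_equal(got$split, want$split)
      expect_equal(got$gain, want$gain)
    }
  })
})

test_that("single-class responses are rejected as degenerate", {
  X <- data.frame(x = rnorm(30))
  expect_error(fit_brt(X, rep(1, 30)), "degenerate")
})

test_that("an uninformative balanced problem stays at the null model", {
  withr::with_seed(11, {
    n <- 200
    X <- data.frame(x = rnorm(n))
    y <- rep(c(0, 1), n / 2)
    m <- fit_brt(X, y, brt_params(learning_rate = 0.01, max_trees = 20,
                                  holdout_fraction = 0, seed = 1))
    p <- predict(m, X)
    expect_equal(mean(p), 0.5, tolerance = 0.02)
    expect_true(all(abs(p - 0.5) < 0.15))
    # training deviance stays near the null model's 2 n log 2
    expect_equal(utils::tail(m$train_deviance, 1), 2 * n * log(2),
                 tolerance = 0.05)
    expect_equal(podomap:::bernoulli_deviance(y, rep(0.5, n)), 2 * n * log(2))
  })
})

test_that("training deviance is non-increasing without bagging", {
  sim <- small_sim(seed = 14, rows = 32, cols = 32, districts = 24)
  des <- sim_design(sim)
  m <- fit_brt(des[model_covariates()], des$presence,
               brt_params(learning_rate = 0.05, bag_fraction = 1,
                          max_trees = 80, holdout_fraction = 0, seed = 3))
  expect_true(all(diff(m$train_deviance) <= 1e-8))
  expect_length(m$train_deviance, m$n_trees)
})

test_that("prediction is the shrunken sum of tree outputs over the intercept", {
  # hand-built 2-tree model, verified by manual traversal
  t1 <- structure(rbind(
    c(var = 1, split = 0.5, left = 2, right = 3, value = 0, n = 10, improvement = 1),
    c(0, NA, 0, 0, -1.0, 5, 0),
    c(0, NA, 0, 0, 2.0, 5, 0)
  ), class = "pod_tree")
  t2 <- structure(rbind(
    c(var = 2, split = 10, left = 2, right = 3, value = 0, n = 10, improvement = 1),
    c(0, NA, 0, 0, 0.5, 5, 0),
    c(0, NA, 0, 0, -0.25, 5, 0)
  ), class = "pod_tree")
  m <- structure(list(intercept = 0.3, trees = list(t1, t2), learning_rate = 0.1,
                      covariates = c("u", "v"), n_trees = 2L,
                      params = brt_params(), data = cbind(u = c(0, 1), v = c(5, 20))),
                 class = "pod_brt")
  nd <- data.frame(u = c(0.2, 0.9), v = c(20, 5))
  # row 1: u<=0.5 -> -1; v>10 -> -0.25 => 0.3 + 0.1*(-1.25) = 0.175
  # row 2: u>0.5 -> +2; v<=10 -> +0.5 => 0.3 + 0.1*(2.5) = 0.55
  expect_equal(predict(m, nd, scale = "logit"), c(0.175, 0.55))
  expect_equal(predict(m, nd), plogis(c(0.175, 0.55)))
  expect_error(predict(m, data.frame(u = 1)), "v")
})

test_that("a treeless model predicts the training prevalence", {
  m <- structure(list(intercept = qlogis(0.3), trees = list(), learning_rate = 0.1,
                      covariates = "u", n_trees = 0L, params = brt_params(),
                      data = cbind(u = 1)),
                 class = "pod_brt")
  expect_equal(predict(m, data.frame(u = 5)), 0.3)
})

test_that("relative influence normalises to 100 and isolates single covariates", {
  sim <- small_sim(seed = 15, rows = 32, cols = 32, districts = 24)
  des <- sim_design(sim)
  m <- fit_brt(des[model_covariates()], des$presence,
               brt_params(learning_rate = 0.05, max_trees = 60,
                          holdout_fraction = 0, seed = 5))
  infl <- relative_influence(m)
  expect_equal(sum(infl$influence), 100, tolerance = 1e-9)
  m1 <- fit_brt(des["precipitation"], des$presence,
                brt_params(learning_rate = 0.05, max_trees = 30,
                           holdout_fraction = 0, seed = 5))
  i1 <- relative_influence(m1)
  expect_equal(i1$influence[i1$covariate == "precipitation"], 100)
})

test_that("partial dependence equals the brute-force per-row averaging oracle", {
  sim <- small_sim(seed = 16, rows = 32, cols = 32, districts = 35)
  des <- utils::head(sim_design(sim), 50)
  m <- fit_brt(des[model_covariates()], des$presence,
               brt_params(learning_rate = 0.1, max_trees = 25, min_obs = 2,
                          holdout_fraction = 0, seed = 2))
  grid <- seq(min(m$data[, "elevation"]), max(m$data[, "elevation"]),
              length.out = 11)
  pd <- partial_dependence(m, "elevation", grid = grid)
  oracle <- vapply(grid, function(v) {
    Xv <- m$data
    Xv[, "elevation"] <- v
    mean(predict(m, Xv, scale = "logit"))
  }, numeric(1))
  expect_equal(pd$logit, oracle)
})

test_that("partial dependence of a single-covariate model is its prediction curve", {
  sim <- small_sim(seed = 17, rows = 32, cols = 32, districts = 24)
  des <- sim_design(sim)
  m <- fit_brt(des["precipitation"], des$presence,
               brt_params(learning_rate = 0.1, max_trees = 40,
                          holdout_fraction = 0, seed = 2))
  grid <- seq(300, 2200, length.out = 25)
  pd <- partial_dependence(m, "precipitation", grid = grid)
  expect_equal(pd$logit,
               predict(m, data.frame(precipitation = grid), scale = "logit"))
})

test_that("partial dependence is flat for a covariate the model never splits on", {
  tree <- structure(rbind(
    c(var = 1, split = 0, left = 2, right = 3, value = 0, n = 8, improvement = 1),
    c(0, NA, 0, 0, -1, 4, 0),
    c(0, NA, 0, 0, 1, 4, 0)
  ), class = "pod_tree")
  m <- structure(list(intercept = 0.2, trees = list(tree), learning_rate = 0.1,
                      covariates = c("u", "v"), n_trees = 1L,
                      params = brt_params(),
                      data = cbind(u = rnorm(8), v = rnorm(8))),
                 class = "pod_brt")
  pd <- partial_dependence(m, "v", n_grid = 9)
  expect_equal(diff(range(pd$logit)), 0)
  expect_equal(pd$logit[1], mean(predict(m, m$data, scale = "logit")))
  expect_error(partial_dependence(m, "w"), "not in the model")
})

test_that("JSON serialisation round-trips predictions bit-faithfully", {
  sim <- small_sim(seed = 19, rows = 32, cols = 32, districts = 24)
  des <- sim_design(sim)
  m <- fit_brt(des[model_covariates()], des$presence,
               brt_params(learning_rate = 0.05, max_trees = 30, seed = 6))
  f <- withr::local_tempfile(fileext = ".json")
  write_brt(m, f)
  m2 <- read_brt(f)
  expect_identical(predict(m2, des[model_covariates()], scale = "logit"),
                   predict(m, des[model_covariates()], scale = "logit"))
  expect_identical(m2$intercept, m$intercept)
  expect_equal(m2$n_trees, m$n_trees)
})

test_that("permuting an uninformative covariate barely moves holdout AUC", {
  sim <- small_sim(seed = 23, rows = 48, cols = 48, districts = 40)
  des <- sim_design(sim)
  noise <- withr::with_seed(2, rnorm(nrow(des)))
  X <- cbind(des[c("precipitation", "elevation", "pop_density")], noise = noise)
  m <- fit_brt(X, des$presence,
               brt_params(learning_rate = 0.05, max_trees = 150, seed = 8))
  ho <- m$holdout_idx
  auc0 <- roc(predict(m, X[ho, ]), des$presence[ho])$auc
  Xp <- X
  Xp$noise <- withr::with_seed(3, sample(Xp$noise))
  auc1 <- roc(predict(m, Xp[ho, ]), des$presence[ho])$auc
  expect_lt(abs(auc1 - auc0), 0.03)
})

test_that("a small learning rate with more trees generalises at least as well", {
  # equal total shrinkage (0.05 x 600 = 0.5 x 60), fixed tree counts, a
  # common holdout; the property holds in aggregate over datasets, so the
  # smoke test pools three seeded studies
  dev_slow <- 0
  dev_fast <- 0
  for (sd in c(30, 24, 31)) {
    sim <- small_sim(seed = sd, rows = 64, cols = 64, districts = 100)
    des <- sim_design(sim)
    X <- des[model_covariates()]
    n <- nrow(X)
    ho <- withr::with_seed(1, sample.int(n, round(0.25 * n)))
    tr <- setdiff(seq_len(n), ho)
    dev_at <- function(lr, nt) {
      m <- fit_brt(X[tr, ], des$presence[tr],
                   brt_params(learning_rate = lr, max_trees = nt,
                              holdout_fraction = 0, seed = 9))
      podomap:::bernoulli_deviance(des$presence[ho], predict(m, X[ho, ]))
    }
    dev_slow <- dev_slow + dev_at(0.05, 600)
    dev_fast <- dev_fast + dev_at(0.5, 60)
  }
  expect_lte(dev_slow, dev_fast + 1e-8)
})
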
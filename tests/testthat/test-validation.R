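# Mann-Whitney rank-statistic oracle for the AUC, ties counted 1/2
auc_rank_oracle <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

test_that("ROC handles perfect separation and random scores", {
  expect_equal(roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  withr::with_seed(8, {
    n <- 2000
    r <- roc(runif(n), rbinom(n, 1, 0.5))
    expect_lt(abs(r$auc - 0.5), 0.03)
  })
  expect_error(roc(1:4, rep(1, 4)), "single class")
})

test_that("trapezoidal AUC equals the rank-statistic oracle on random instances", {
  withr::with_seed(12, {
    for (i in 1:50) {
      n <- sample(20:80, 1)
      scores <- round(runif(n), 2)  # rounding forces ties
      labels <- rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      expect_equal(roc(scores, labels)$auc, auc_rank_oracle(scores, labels))
    }
  })
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(13, {
    scores <- rnorm(100)
    labels <- rbinom(100, 1, plogis(scores))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    a <- roc(scores, labels)$auc
    expect_equal(roc(exp(scores), labels)$auc, a)
    expect_equal(roc(10 * scores - 3, labels)$auc, a)
  })
})

test_that("ROC sensitivity falls and specificity rises along the threshold axis", {
  withr::with_seed(14, {
    scores <- runif(300)
    labels <- rbinom(300, 1, scores)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    cv <- roc(scores, labels)$curve
    o <- order(cv$threshold)
    expect_true(all(diff(cv$sensitivity[o]) <= 1e-12))
    expect_true(all(diff(cv$specificity[o]) >= -1e-12))
  })
})

test_that("confusion statistics reproduce the hand-built 2x2 table", {
  # TP=40, FN=10, FP=20, TN=30 at tau = 0.5
  scores <- c(rep(0.9, 40), rep(0.1, 10), rep(0.9, 20), rep(0.1, 30))
  labels <- c(rep(1, 50), rep(0, 50))
  s <- confusion_stats(scores, labels, 0.5)
  expect_equal(s$pcc, 0.70)
  expect_equal(s$sensitivity, 0.80)
  expect_equal(s$specificity, 0.60)
  # kappa by hand: pe = 0.6*0.5 + 0.4*0.5 = 0.5 -> (0.7-0.5)/0.5 = 0.4
  expect_equal(s$kappa, 0.4)
  expect_error(confusion_stats(scores, labels, 1.5), "0, 1")
})

test_that("kappa is 1 for perfect prediction, ~0 for independence, 0 when degenerate", {
  perfect <- confusion_stats(c(1, 1, 0, 0), c(1, 1, 0, 0), 0.5)
  expect_equal(perfect$pcc, 1)
  expect_equal(perfect$kappa, 1)
  withr::with_seed(15, {
    n <- 4000
    ind <- confusion_stats(runif(n), rbinom(n, 1, 0.5), 0.5)
    expect_equal(ind$kappa, 0, tolerance = 0.05)
  })
  # constant predicted class: degenerate marginals give 0, not NaN
  allpos <- confusion_stats(rep(0.9, 10), rep(c(0, 1), 5), 0.5)
  expect_equal(allpos$kappa, 0)
})

test_that("threshold selection maximises sensitivity + specificity + PCC", {
  # perfect separation: the smallest candidate achieving the maximum
  sep <- select_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(sep$threshold, 0.8)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  expect_equal(sep$pcc, 1)
  # exhaustive-search oracle on random instances
  withr::with_seed(16, {
    for (i in 1:30) {
      n <- sample(15:60, 1)
      scores <- round(runif(n), 1)
      labels <- rbinom(n, 1, scores)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      got <- select_threshold(scores, labels)
      cand <- c(sort(unique(scores)), Inf)
      objs <- vapply(cand, function(t) {
        s <- podomap:::confusion_at(scores, labels, t)
        s[["sensitivity"]] + s[["specificity"]] + s[["pcc"]]
      }, numeric(1))
      expect_equal(got$objective, max(objs))
      expect_equal(got$threshold, cand[which.max(objs)])
      # returned objective dominates every candidate
      expect_true(all(got$objective >= objs - 1e-12))
    }
  })
})

test_that("shifting all scores shifts the threshold, not the statistics", {
  withr::with_seed(17, {
    scores <- runif(80)
    labels <- rbinom(80, 1, scores)
    a <- select_threshold(scores, labels)
    b <- select_threshold(scores + 3, labels)
    expect_equal(b$threshold, a$threshold + 3)
    expect_equal(b$sensitivity, a$sensitivity)
    expect_equal(b$pcc, a$pcc)
  })
})

test_that("AUC interpretation bands use left-closed edges", {
  expect_equal(auc_band(0.84), "excellent")
  expect_equal(auc_band(0.69), "poor")
  expect_equal(auc_band(0.9), "outstanding")
  expect_equal(auc_band(c(0.7, 0.8, 1.0)),
               c("acceptable", "excellent", "outstanding"))
})

test_that("out-of-bootstrap cross-validation summarises per-submodel statistics", {
  sim <- small_sim(seed = 36, rows = 48, cols = 48, districts = 40)
  des <- sim_design(sim)
  ens <- fit_ensemble(des[model_covariates()], des$presence,
                      brt_params(learning_rate = 0.1, max_trees = 40, seed = 1),
                      n_submodels = 5, base_seed = 11)
  cv <- cross_validate_ensemble(ens)
  expect_equal(nrow(cv$per_submodel), 5L)
  # sd of the AUC matches the direct formula
  expect_equal(cv$summary$sd[cv$summary$statistic == "auc"],
               stats::sd(cv$per_submodel$auc))
  expect_true(all(cv$summary$q_low <= cv$summary$q_high))
  # single submodel: mean equals its statistic, degenerate interval
  one <- structure(list(submodels = ens$submodels[1], X = ens$X, y = ens$y,
                        base_seed = 1L, params = ens$params),
                   class = "pod_ensemble")
  cv1 <- cross_validate_ensemble(one)
  expect_equal(cv1$summary$mean[cv1$summary$statistic == "auc"],
               cv1$per_submodel$auc[1])
  expect_equal(cv1$summary$q_low[cv1$summary$statistic == "auc"],
               cv1$summary$q_high[cv1$summary$statistic == "auc"])
})

test_that("external validation scores independent points on the mean map", {
  # a perfect map: suitability equals the true presence pattern
  v <- matrix(c(0.9, 0.9, 0.1, 0.1, 0.9, 0.1, 0.1, 0.1, 0.9,
                0.1, 0.9, 0.1, 0.1, 0.1, 0.9, 0.9), 4, 4)
  map <- pod_raster(v, cell_size = 1)
  xy <- raster_xy(map)
  pts <- tibble::tibble(lon = xy$x, lat = xy$y,
                        presence = as.integer(xy$value > 0.5))
  ext <- external_validate(map, pts)
  expect_equal(ext$auc, 1)
  expect_equal(ext$band, "outstanding")
  # shuffled labels drop the AUC to chance
  withr::with_seed(18, {
    big <- pod_raster(matrix(runif(900), 30, 30), cell_size = 1)
    bxy <- raster_xy(big)
    bpts <- tibble::tibble(lon = bxy$x, lat = bxy$y,
                           presence = sample(rep(0:1, 450)))
    expect_equal(external_validate(big, bpts)$auc, 0.5, tolerance = 0.05)
  })
  expect_error(external_validate(map, tibble::tibble(lon = 99, lat = 1, presence = 1)),
               "outside")
})
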
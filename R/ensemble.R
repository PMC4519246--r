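#' Fit a bootstrap ensemble of BRT submodels
#'
#' Submodel `i` is fitted to a bootstrap resample (with replacement, same
#' size) of the presence/absence sites, seeded at `base_seed + i`; resamples
#' that contain a single class are redrawn up to `max_retries` times before
#' erroring. The spread of the submodels' predictions carries the
#' uncertainty that the ensemble maps and bootstrap envelopes report.
#'
#' @param X data frame or matrix of site covariates.
#' @param y 0/1 presence labels.
#' @param params shared [brt_params()] (each submodel's seed is overridden
#'   with `base_seed + i`).
#' @param n_submodels ensemble size (120 in a full analysis; scale down for
#'   quick runs).
#' @param base_seed integer base seed.
#' @param max_retries redraw attempts for single-class resamples.
#' @return an object of class `pod_ensemble`: a list of `pod_brt` submodels
#'   (each carrying `boot_idx` and `oob_idx`), plus the training data.
#' @export
fit_ensemble <- function(X, y, params = brt_params(), n_submodels = 120L,
                         base_seed = 1L, max_retries = 20L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("degenerate response: only one class present", call. = FALSE)
  n <- nrow(X)
  submodels <- vector("list", n_submodels)
  for (i in seq_len(n_submodels)) {
    seed_i <- base_seed + i
    idx <- with_pod_seed(seed_i, {
      got <- NULL
      for (try in seq_len(max_retries)) {
        cand <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[cand])) == 2L) { got <- cand; break }
      }
      got
    })
    if (is.null(idx)) {
      stop("could not draw a two-class bootstrap resample after ",
           max_retries, " attempts (submodel ", i, ")", call. = FALSE)
    }
    p_i <- params
    p_i$seed <- as.integer(seed_i)
    m <- fit_brt(X[idx, , drop = FALSE], y[idx], p_i)
    m$boot_idx <- idx
    m$oob_idx <- setdiff(seq_len(n), unique(idx))
    submodels[[i]] <- m
  }
  structure(list(submodels = submodels, X = X, y = y,
                 base_seed = as.integer(base_seed), params = params),
            class = "pod_ensemble")
}

#' @export
print.pod_ensemble <- function(x, ...) {
  nt <- vapply(x$submodels, `[[`, integer(1), "n_trees")
  cat(sprintf("<pod_ensemble> %d BRT submodels on %d sites (%d-%d trees each)\n",
              length(x$submodels), nrow(x$X), min(nt), max(nt)))
  invisible(x)
}

# per-row type-7 quantile (linear interpolation between order statistics)
row_quantile <- function(M, p) {
  n <- ncol(M)
  S <- matrix(M[order(row(M), M)], nrow(M), byrow = TRUE)
  h <- (n - 1) * p + 1
  j <- floor(h)
  g <- h - j
  if (j >= n) S[, n] else (1 - g) * S[, j] + g * S[, j + 1]
}

#' Ensemble suitability, quantile, and uncertainty maps
#'
#' Evaluates every submodel's probability at each land pixel of the stack
#' and reduces across submodels: the arithmetic mean map, empirical 2.5% and
#' 97.5% per-pixel quantile maps, and the uncertainty map (the range of that
#' 95% interval). Non-land and nodata cells stay nodata, never 0.
#'
#' @param ensemble a `pod_ensemble` (or plain list of `pod_brt`).
#' @param stack an aligned [pod_stack] containing the model covariates.
#' @param level central interval mass for the quantile maps (default 0.95).
#' @return an object of class `pod_ensemble_maps`: `mean_map`, `q_low_map`,
#'   `q_high_map`, `uncertainty_map` ([pod_raster]s) and `design` (the land
#'   pixels evaluated).
#' @export
predict_maps <- function(ensemble, stack, level = 0.95) {
  submodels <- if (inherits(ensemble, "pod_ensemble")) ensemble$submodels else ensemble
  covs <- submodels[[1]]$covariates
  design <- stack_design(stack, covs)
  if (nrow(design) == 0L) stop("no land pixels with complete covariates", call. = FALSE)
  P <- vapply(submodels, function(m) predict.pod_brt(m, design, "probability"),
              numeric(nrow(design)))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  alpha <- (1 - level) / 2
  tmpl <- stack$land_mask
  as_map <- function(vals) {
    m <- matrix(NA_real_, nrow(tmpl$values), ncol(tmpl$values))
    m[cbind(design$row, design$col)] <- vals
    pod_raster(m, origin_x = tmpl$origin_x, origin_y = tmpl$origin_y,
               cell_size = tmpl$cell_size)
  }
  q_low <- row_quantile(P, alpha)
  q_high <- row_quantile(P, 1 - alpha)
  structure(
    list(mean_map = as_map(rowMeans(P)),
         q_low_map = as_map(q_low),
         q_high_map = as_map(q_high),
         uncertainty_map = as_map(q_high - q_low),
         design = design, level = level,
         n_submodels = length(submodels)),
    class = "pod_ensemble_maps"
  )
}

#' Pooled relative influence across the ensemble
#'
#' Per-covariate mean and percentile interval of [relative_influence()]
#' across submodels; means are renormalised to sum to 100.
#'
#' @param ensemble a `pod_ensemble` or list of `pod_brt`.
#' @param level central interval mass (default 0.95).
#' @return a tibble: `covariate`, `mean_influence`, `q_low`, `q_high`,
#'   sorted by decreasing mean influence.
#' @export
ensemble_influence <- function(ensemble, level = 0.95) {
  submodels <- if (inherits(ensemble, "pod_ensemble")) ensemble$submodels else ensemble
  per <- purrr::map_dfr(seq_along(submodels), function(i) {
    dplyr::mutate(relative_influence(submodels[[i]]), submodel = i)
  })
  alpha <- (1 - level) / 2
  out <- per |>
    dplyr::group_by(.data$covariate) |>
    dplyr::summarise(
      mean_influence = mean(.data$influence),
      q_low = stats::quantile(.data$influence, alpha, names = FALSE),
      q_high = stats::quantile(.data$influence, 1 - alpha, names = FALSE),
      .groups = "drop"
    )
  out$mean_influence <- 100 * out$mean_influence / sum(out$mean_influence)
  dplyr::arrange(out, dplyr::desc(.data$mean_influence))
}

#' Marginal-effect curves with bootstrap envelopes
#'
#' Computes each submodel's partial-dependence curve on a common grid (100
#' evenly spaced points over the pooled observed range by default) and
#' summarises pointwise: the mean marginal effect and the 2.5%/97.5%
#' bootstrap envelope, on the logit scale.
#'
#' @param ensemble a `pod_ensemble` or list of `pod_brt`.
#' @param covariates covariate names (default: all model covariates).
#' @param n_grid grid size per covariate.
#' @param level envelope mass (default 0.95).
#' @return a tibble: `covariate`, `value`, `mean_logit`, `q_low`, `q_high`.
#' @export
ensemble_marginal_curves <- function(ensemble, covariates = NULL,
                                     n_grid = 100L, level = 0.95) {
  submodels <- if (inherits(ensemble, "pod_ensemble")) ensemble$submodels else ensemble
  if (is.null(covariates)) covariates <- submodels[[1]]$covariates
  alpha <- (1 - level) / 2
  purrr::map_dfr(covariates, function(cv) {
    rng <- range(vapply(submodels, function(m) range(m$data[, cv]), numeric(2)))
    grid <- seq(rng[1], rng[2], length.out = n_grid)
    curves <- vapply(submodels,
                     function(m) partial_dependence(m, cv, grid = grid)$logit,
                     numeric(n_grid))
    if (is.null(dim(curves))) curves <- matrix(curves, nrow = 1L)
    tibble::tibble(
      covariate = cv,
      value = grid,
      mean_logit = rowMeans(curves),
      q_low = row_quantile(curves, alpha),
      q_high = row_quantile(curves, 1 - alpha)
    )
  })
}

#' Smoothed prevalence against an environmental covariate
#'
#' Degree-1 local polynomial (tricube kernel) regression of community
#' prevalence on a covariate, with a pointwise normal-approximation
#' interval from the weighted fit — the standard exploratory view of how
#' prevalence tracks altitude, rainfall, or soil composition.
#'
#' @param prevalence community prevalences (fractions or percent).
#' @param covariate covariate value at each community.
#' @param bandwidth smoothing bandwidth as the fraction of points entering
#'   each local fit (loess span), > 0.
#' @param n_grid evaluation grid size.
#' @param level interval mass.
#' @return a tibble: `value`, `fit`, `low`, `high`.
#' @export
prevalence_vs_covariate <- function(prevalence, covariate, bandwidth = 0.75,
                                    n_grid = 50L, level = 0.95) {
  if (bandwidth <= 0) stop("`bandwidth` must be positive", call. = FALSE)
  if (length(prevalence) < 10L) stop("need at least 10 communities", call. = FALSE)
  stopifnot(length(prevalence) == length(covariate))
  df <- data.frame(p = prevalence, x = covariate)
  fit <- stats::loess(p ~ x, data = df, degree = 1L, span = bandwidth,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(covariate), max(covariate), length.out = n_grid)
  pr <- stats::predict(fit, newdata = data.frame(x = grid), se = TRUE)
  z <- stats::qnorm((1 + level) / 2)
  tibble::tibble(
    value = grid,
    fit = as.numeric(pr$fit),
    low = as.numeric(pr$fit - z * pr$se.fit),
    high = as.numeric(pr$fit + z * pr$se.fit)
  )
}
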
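#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted BRT model
#'
#' One row per covariate with its relative influence.
#'
#' @param x a `pod_brt`.
#' @param ... unused.
#' @return a tibble: `covariate`, `influence`.
#' @export
tidy.pod_brt <- function(x, ...) relative_influence(x)

#' @rdname tidy.pod_brt
#' @export
glance.pod_brt <- function(x, ...) {
  tibble::tibble(
    n_trees = x$n_trees,
    learning_rate = x$learning_rate,
    tree_complexity = x$params$tree_complexity,
    train_deviance = utils::tail(x$train_deviance, 1),
    holdout_deviance = if (is.null(x$holdout_deviance)) NA_real_ else
      utils::tail(x$holdout_deviance, 1),
    n_obs = nrow(x$data)
  )
}

#' Tidy an ensemble
#'
#' @param x a `pod_ensemble`.
#' @param ... unused.
#' @return [tidy()]: pooled influence tibble; [glance()]: one-row summary.
#' @export
tidy.pod_ensemble <- function(x, ...) ensemble_influence(x)

#' @rdname tidy.pod_ensemble
#' @export
glance.pod_ensemble <- function(x, ...) {
  nt <- vapply(x$submodels, `[[`, integer(1), "n_trees")
  tibble::tibble(
    n_submodels = length(x$submodels),
    n_obs = nrow(x$X),
    base_seed = x$base_seed,
    mean_trees = mean(nt),
    prevalence = mean(x$y)
  )
}

#' Tidy an ROC result
#'
#' @param x a `pod_roc`.
#' @param ... unused.
#' @return [tidy()]: the threshold-by-threshold curve; [glance()]: AUC and
#'   its interpretation band.
#' @export
tidy.pod_roc <- function(x, ...) x$curve

#' @rdname tidy.pod_roc
#' @export
glance.pod_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, band = auc_band(x$auc))
}

#' Tidy a cross-validation summary
#'
#' @param x a `pod_validation`.
#' @param ... unused.
#' @return [tidy()]: per-submodel statistics; [glance()]: the pooled summary
#'   in wide form.
#' @export
tidy.pod_validation <- function(x, ...) x$per_submodel

#' @rdname tidy.pod_validation
#' @export
glance.pod_validation <- function(x, ...) {
  s <- x$summary
  out <- tibble::as_tibble(as.list(stats::setNames(s$mean, s$statistic)))
  out$n_submodels <- nrow(x$per_submodel)
  out
}
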
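#' Plot a raster surface
#'
#' @param object a [pod_raster].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pod_raster <- function(object, ...) {
  df <- raster_xy(object)
  ggplot2::ggplot(df[!is.na(df$value), ],
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
plot.pod_raster <- function(x, ...) print(autoplot.pod_raster(x, ...))

#' Plot the ROC curve
#'
#' @param object a `pod_roc`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pod_roc <- function(object, ...) {
  df <- object$curve[order(object$curve$threshold, decreasing = TRUE), ]
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("AUC = %.3f (%s)", object$auc, auc_band(object$auc))
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.pod_roc <- function(x, ...) print(autoplot.pod_roc(x, ...))

#' Plot pooled relative influence with ensemble intervals
#'
#' @param influence a tibble from [ensemble_influence()].
#' @return a ggplot.
#' @export
plot_influence <- function(influence) {
  df <- dplyr::mutate(influence,
                      covariate = stats::reorder(.data$covariate, .data$mean_influence))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_influence, y = .data$covariate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$q_low, xmax = .data$q_high), height = 0.25
    ) +
    ggplot2::labs(x = "relative influence (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot marginal-effect curves with bootstrap envelopes
#'
#' @param curves a tibble from [ensemble_marginal_curves()].
#' @return a ggplot faceted by covariate.
#' @export
plot_marginal_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q_low, ymax = .data$q_high),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_logit)) +
    ggplot2::facet_wrap(~covariate, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "marginal effect (logit)") +
    ggplot2::theme_minimal()
}

#' Plot a smoothed prevalence-covariate relationship
#'
#' @param curve a tibble from [prevalence_vs_covariate()].
#' @param xlab x-axis label.
#' @return a ggplot.
#' @export
plot_prevalence_curve <- function(curve, xlab = "covariate") {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$low, ymax = .data$high),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::labs(x = xlab, y = "prevalence") +
    ggplot2::theme_minimal()
}
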
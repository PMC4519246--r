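# confusion statistics at one threshold (classification rule: score >= tau),
# without the [0,1] range check so threshold searches can use raw candidates
confusion_at <- function(scores, labels, tau) {
  pred <- scores >= tau
  pos <- labels == 1
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  fp <- sum(pred & !pos); tn <- sum(!pred & !pos)
  n <- length(labels)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  pcc <- (tp + tn) / n
  pe <- ((tp + fp) / n) * ((tp + fn) / n) + ((fn + tn) / n) * ((fp + tn) / n)
  kappa <- if (abs(1 - pe) < 1e-12) 0 else (pcc - pe) / (1 - pe)
  c(sensitivity = sens, specificity = spec, pcc = pcc, kappa = kappa)
}

#' Receiver operating characteristic curve
#'
#' Evaluates sensitivity, specificity and proportion correctly classified at
#' every unique score (plus -Inf/+Inf sentinels) under the rule
#' "predict presence iff score >= threshold", and the AUC by the trapezoidal
#' rule over (1 - specificity, sensitivity) — equal to the Mann-Whitney rank
#' statistic with tied scores contributing 1/2.
#'
#' @param scores numeric prediction scores (any monotone scale).
#' @param labels 0/1 observed presence (both classes required).
#' @return an object of class `pod_roc`: a list with `curve` (tibble of
#'   `threshold`, `sensitivity`, `specificity`, `pcc`) and `auc`.
#' @export
roc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L) {
    stop("labels contain a single class", call. = FALSE)
  }
  thr <- c(-Inf, sort(unique(scores)), Inf)
  stats_tab <- t(vapply(thr, function(t) confusion_at(scores, labels, t),
                        numeric(4)))
  curve <- tibble::tibble(
    threshold = thr,
    sensitivity = stats_tab[, "sensitivity"],
    specificity = stats_tab[, "specificity"],
    pcc = stats_tab[, "pcc"]
  )
  # thresholds descend along the ROC curve so FPR ascends
  o <- order(curve$threshold, decreasing = TRUE)
  fpr <- 1 - curve$specificity[o]
  tpr <- curve$sensitivity[o]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(curve = curve, auc = auc), class = "pod_roc")
}

#' @export
print.pod_roc <- function(x, ...) {
  cat(sprintf("<pod_roc> AUC %.3f (%s), %d thresholds\n",
              x$auc, auc_band(x$auc), nrow(x$curve)))
  invisible(x)
}

#' Confusion statistics at a probability threshold
#'
#' Predicted presence iff score >= `tau`. Reports sensitivity TP/(TP+FN),
#' specificity TN/(TN+FP), proportion correctly classified (TP+TN)/n, and
#' Cohen's kappa (PCC - Pe)/(1 - Pe) with chance agreement Pe from the
#' marginals (0 when the marginals are degenerate).
#'
#' @param scores probability scores.
#' @param labels 0/1 observed presence.
#' @param tau threshold in `[0, 1]`.
#' @return a one-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `pcc`, `kappa`.
#' @export
confusion_stats <- function(scores, labels, tau) {
  if (length(tau) != 1L || is.na(tau) || tau < 0 || tau > 1) {
    stop("`tau` must be a single value in [0, 1]", call. = FALSE)
  }
  s <- confusion_at(scores, as.numeric(labels), tau)
  tibble::tibble(threshold = tau, sensitivity = s[["sensitivity"]],
                 specificity = s[["specificity"]], pcc = s[["pcc"]],
                 kappa = s[["kappa"]])
}

#' Optimal occurrence threshold from the ROC curve
#'
#' Selects the threshold maximising the unweighted sum of sensitivity,
#' specificity and PCC over all candidate thresholds (the unique scores plus
#' +Inf); exact ties go to the smallest threshold. Youden's J
#' (sensitivity + specificity - 1) is available as an alternative objective.
#'
#' @param scores prediction scores.
#' @param labels 0/1 observed presence (both classes required).
#' @param objective `"sum"` (sensitivity + specificity + PCC) or `"youden"`.
#' @return a one-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `pcc`, `kappa`, `objective`.
#' @export
select_threshold <- function(scores, labels, objective = c("sum", "youden")) {
  objective <- match.arg(objective)
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) {
    stop("labels contain a single class", call. = FALSE)
  }
  cand <- c(sort(unique(scores)), Inf)
  stats_tab <- t(vapply(cand, function(t) confusion_at(scores, labels, t),
                        numeric(4)))
  obj <- if (objective == "sum") {
    stats_tab[, "sensitivity"] + stats_tab[, "specificity"] + stats_tab[, "pcc"]
  } else {
    stats_tab[, "sensitivity"] + stats_tab[, "specificity"] - 1
  }
  i <- which.max(obj)  # first maximum = smallest threshold
  tibble::tibble(
    threshold = cand[i],
    sensitivity = unname(stats_tab[i, "sensitivity"]),
    specificity = unname(stats_tab[i, "specificity"]),
    pcc = unname(stats_tab[i, "pcc"]),
    kappa = unname(stats_tab[i, "kappa"]),
    objective = unname(obj[i])
  )
}

#' Discriminatory-performance band of an AUC
#'
#' Standard interpretation bands: below 0.7 poor, 0.7 to 0.8 acceptable,
#' 0.8 to 0.9 excellent, 0.9 and above outstanding (bands are closed on the
#' left).
#'
#' @param auc AUC value(s) in `[0, 1]`.
#' @return character vector of band labels.
#' @export
auc_band <- function(auc) {
  stopifnot(all(auc >= 0 & auc <= 1))
  as.character(cut(auc, breaks = c(-Inf, 0.7, 0.8, 0.9, Inf), right = FALSE,
                   labels = c("poor", "acceptable", "excellent", "outstanding")))
}

#' Out-of-bootstrap cross-validation of the ensemble
#'
#' Scores every submodel on the sites left out of its bootstrap resample:
#' AUC, plus PCC, sensitivity, specificity and kappa at the submodel's own
#' optimal threshold. Reports each statistic's mean, standard deviation and
#' percentile interval across submodels.
#'
#' @param ensemble a `pod_ensemble`.
#' @param level interval mass (default 0.95).
#' @return an object of class `pod_validation`: `per_submodel` (tibble) and
#'   `summary` (tibble of `statistic`, `mean`, `sd`, `q_low`, `q_high`).
#' @export
cross_validate_ensemble <- function(ensemble, level = 0.95) {
  stopifnot(inherits(ensemble, "pod_ensemble"))
  per <- purrr::map_dfr(seq_along(ensemble$submodels), function(i) {
    m <- ensemble$submodels[[i]]
    oob <- m$oob_idx
    if (length(oob) < 2L || length(unique(ensemble$y[oob])) < 2L) {
      return(tibble::tibble(submodel = i, auc = NA_real_, threshold = NA_real_,
                            sensitivity = NA_real_, specificity = NA_real_,
                            pcc = NA_real_, kappa = NA_real_))
    }
    sc <- predict.pod_brt(m, ensemble$X[oob, , drop = FALSE], "probability")
    yy <- ensemble$y[oob]
    r <- roc(sc, yy)
    th <- select_threshold(sc, yy)
    tibble::tibble(submodel = i, auc = r$auc, threshold = th$threshold,
                   sensitivity = th$sensitivity, specificity = th$specificity,
                   pcc = th$pcc, kappa = th$kappa)
  })
  alpha <- (1 - level) / 2
  summ <- per |>
    tidyr::pivot_longer(-"submodel", names_to = "statistic") |>
    dplyr::group_by(.data$statistic) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      q_low = stats::quantile(.data$value, alpha, na.rm = TRUE, names = FALSE),
      q_high = stats::quantile(.data$value, 1 - alpha, na.rm = TRUE, names = FALSE),
      .groups = "drop"
    )
  structure(list(per_submodel = per, summary = summ, level = level),
            class = "pod_validation")
}

#' @export
print.pod_validation <- function(x, ...) {
  cat(sprintf("<pod_validation> %d submodels (out-of-bootstrap)\n",
              nrow(x$per_submodel)))
  print(x$summary)
  invisible(x)
}

#' External validation against independent presence/absence records
#'
#' Extracts the predicted suitability of the mean ensemble map at
#' independent survey points and reports the AUC of observed presence
#' against it, with its interpretation band.
#'
#' @param mean_map suitability [pod_raster].
#' @param points data frame with `lon`, `lat`, `presence` (0/1); points must
#'   fall inside the map extent.
#' @return a list of class `pod_external`: `auc`, `band`, `roc`, `n_used`
#'   (points on nodata cells are excluded and counted in `n_dropped`).
#' @export
external_validate <- function(mean_map, points) {
  stopifnot(all(c("lon", "lat", "presence") %in% names(points)))
  inside <- raster_contains(mean_map, points$lon, points$lat)
  if (any(!inside)) {
    stop(sum(!inside), " validation point(s) fall outside the map extent",
         call. = FALSE)
  }
  idx <- raster_cell_index(mean_map, points$lon, points$lat)
  sc <- mean_map$values[cbind(idx$row, idx$col)]
  ok <- !is.na(sc)
  r <- roc(sc[ok], points$presence[ok])
  structure(list(auc = r$auc, band = auc_band(r$auc), roc = r,
                 n_used = sum(ok), n_dropped = sum(!ok)),
            class = "pod_external")
}

#' @export
print.pod_external <- function(x, ...) {
  cat(sprintf("<pod_external> AUC %.3f (%s) on %d independent records\n",
              x$auc, x$band, x$n_used))
  invisible(x)
}
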
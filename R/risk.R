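#' Binarize a suitability map at a threshold
#'
#' Cells with suitability >= `tau` become 1 (inside the occurrence limits),
#' cells below become 0, nodata is preserved. The >= rule matches the
#' classification rule used in threshold selection.
#'
#' @param suitability probability [pod_raster].
#' @param tau threshold in `[0, 1]`.
#' @return a 0/1 [pod_raster] (kind categorical).
#' @export
binarize <- function(suitability, tau) {
  if (length(tau) != 1L || is.na(tau) || tau < 0 || tau > 1) {
    stop("`tau` must be a single value in [0, 1]", call. = FALSE)
  }
  v <- suitability$values
  out <- ifelse(is.na(v), NA_real_, as.numeric(v >= tau))
  pod_raster(matrix(out, nrow(v), ncol(v)), origin_x = suitability$origin_x,
             origin_y = suitability$origin_y, cell_size = suitability$cell_size,
             kind = "categorical")
}

#' Binary occurrence-limit maps with uncertainty bounds
#'
#' Applies one threshold to the ensemble mean map and to its 2.5% and 97.5%
#' quantile maps, giving the point-estimate limits and their lower/upper
#' bounds. Because the quantile maps are ordered, the bound maps nest:
#' low subset-of mean subset-of high wherever all are defined.
#'
#' @param maps a `pod_ensemble_maps` from [predict_maps()].
#' @param tau threshold in `[0, 1]`.
#' @return an object of class `pod_limits`: `mean_limits`, `low_limits`,
#'   `high_limits` (0/1 [pod_raster]s) and `tau`.
#' @export
occurrence_limits <- function(maps, tau) {
  structure(
    list(mean_limits = binarize(maps$mean_map, tau),
         low_limits = binarize(maps$q_low_map, tau),
         high_limits = binarize(maps$q_high_map, tau),
         tau = tau),
    class = "pod_limits"
  )
}

zonal_sum <- function(values, zones, sel) {
  v <- ifelse(sel, values, 0)
  v[is.na(v)] <- 0
  z <- as.vector(zones)
  ok <- !is.na(z)
  rowsum(as.vector(v)[ok], z[ok])
}

#' Population and landmass inside the occurrence limits, by zone
#'
#' Overlays the binary limits on the gridded population and accumulates, per
#' administrative zone, the population living in suitable cells, the share
#' of the zone population it represents, and the suitable landmass; the
#' lower/upper population bounds come from thresholding the 2.5%/97.5%
#' quantile maps at the same threshold. A `Total` row carries the national
#' sums, which equal the zonal sums exactly.
#'
#' @param limits a `pod_limits` from [occurrence_limits()].
#' @param population [pod_raster] of persons per cell.
#' @param zones categorical [pod_raster] of zone identifiers.
#' @param denominator `"zone"` (percent of each zone's population, used for
#'   zone rows) or `"national"`; the `Total` row always uses the national
#'   population.
#' @return a tibble of class `pod_risk`: `zone`, `population_at_risk`,
#'   `pop_lower`, `pop_upper`, `percent_exposed`, `suitable_area_km2`,
#'   `zone_population`, with the `Total` row last.
#' @export
population_at_risk <- function(limits, population, zones,
                               denominator = c("zone", "national")) {
  denominator <- match.arg(denominator)
  for (g in list(limits$mean_limits, limits$low_limits, limits$high_limits, zones)) {
    if (!raster_same_geometry(g, population)) {
      stop("rasters are not aligned to a common geometry", call. = FALSE)
    }
  }
  pv <- population$values
  zv <- zones$values
  inside <- function(lim) !is.na(lim$values) & lim$values == 1
  par_z <- zonal_sum(pv, zv, inside(limits$mean_limits))
  low_z <- zonal_sum(pv, zv, inside(limits$low_limits))
  high_z <- zonal_sum(pv, zv, inside(limits$high_limits))
  pop_z <- zonal_sum(pv, zv, !is.na(pv))
  cells_z <- zonal_sum((!is.na(pv)) * 1, zv, inside(limits$mean_limits))
  cell_area <- population$cell_size^2

  zone_ids <- rownames(par_z)
  denom <- if (denominator == "zone") pop_z[, 1] else rep(sum(pop_z), length(zone_ids))
  out <- tibble::tibble(
    zone = zone_ids,
    population_at_risk = unname(par_z[, 1]),
    pop_lower = unname(low_z[, 1]),
    pop_upper = unname(high_z[, 1]),
    percent_exposed = unname(ifelse(denom > 0, 100 * par_z[, 1] / denom, 0)),
    suitable_area_km2 = unname(cells_z[, 1] * cell_area),
    zone_population = unname(pop_z[, 1])
  )
  total <- tibble::tibble(
    zone = "Total",
    population_at_risk = sum(out$population_at_risk),
    pop_lower = sum(out$pop_lower),
    pop_upper = sum(out$pop_upper),
    percent_exposed = 100 * sum(out$population_at_risk) / sum(out$zone_population),
    suitable_area_km2 = sum(out$suitable_area_km2),
    zone_population = sum(out$zone_population)
  )
  res <- dplyr::bind_rows(out, total)
  class(res) <- c("pod_risk", class(res))
  attr(res, "tau") <- limits$tau
  res
}

#' Sensitivity of the population at risk to the occurrence threshold
#'
#' Recomputes the national population-at-risk estimate (with bounds) at each
#' threshold in `thresholds`; by construction the estimate is non-increasing
#' in the threshold.
#'
#' @param maps a `pod_ensemble_maps`.
#' @param population [pod_raster] of persons per cell.
#' @param zones zone [pod_raster].
#' @param thresholds numeric thresholds (default the conventional low/high
#'   pair `c(0.3, 0.6)`).
#' @return a tibble: `threshold`, `population_at_risk`, `pop_lower`,
#'   `pop_upper`, `percent_exposed`, `suitable_area_km2`.
#' @export
threshold_sensitivity <- function(maps, population, zones,
                                  thresholds = c(0.3, 0.6)) {
  if (length(thresholds) == 0L) stop("`thresholds` must be non-empty", call. = FALSE)
  purrr::map_dfr(thresholds, function(tau) {
    tab <- population_at_risk(occurrence_limits(maps, tau), population, zones)
    tot <- tab[tab$zone == "Total", ]
    tibble::tibble(
      threshold = tau,
      population_at_risk = tot$population_at_risk,
      pop_lower = tot$pop_lower,
      pop_upper = tot$pop_upper,
      percent_exposed = tot$percent_exposed,
      suitable_area_km2 = tot$suitable_area_km2
    )
  })
}
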
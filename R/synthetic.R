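#' Configuration for the synthetic study area
#'
#' Defines a seeded synthetic analogue of a national mapping survey: a
#' rectangular study area on a planar km grid, spatially autocorrelated
#' environmental covariates, a known "true" suitability surface, and a
#' two-communities-per-district binomial prevalence survey.
#'
#' @param seed integer seed; identical configurations (including the seed)
#'   regenerate bit-identical outputs.
#' @param grid_rows,grid_cols grid dimensions in cells (at least 16).
#' @param cell_size cell edge length in km.
#' @param n_districts number of districts tiling the grid (at least 4).
#' @param communities_per_district communities sampled per district
#'   (default 2, the sampling density of national lymphatic-filariasis-style
#'   mapping surveys).
#' @param mean_sample_size mean examined individuals per community
#'   (default 100; actual sizes are Poisson, clamped to at least 10).
#' @param smoothing_radius Gaussian smoothing radius, in cells, applied to
#'   the white-noise fields (controls the spatial autocorrelation range).
#' @param prevalence_scale multiplier mapping suitability (0-1) to community
#'   prevalence; the default 0.1 keeps community prevalences in the 0-55%
#'   band seen in national lymphoedema surveys.
#' @param flagged_fraction fraction of communities tagged as coming from the
#'   historical survey within an LF-endemic district (these are dropped by
#'   [filter_records()]).
#' @param water_fraction fraction of cells designated water bodies (excluded
#'   from the land mask, used for distance-to-water).
#' @param effect_params named magnitudes of the true suitability terms; see
#'   [true_suitability()].
#' @return an object of class `pod_synth_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             grid_rows = 96L, grid_cols = 96L,
                             cell_size = 1,
                             n_districts = 100L,
                             communities_per_district = 2L,
                             mean_sample_size = 100L,
                             smoothing_radius = 4,
                             prevalence_scale = 0.1,
                             flagged_fraction = 0.1,
                             water_fraction = 0.03,
                             effect_params = default_effect_params()) {
  stopifnot(grid_rows >= 16L, grid_cols >= 16L, n_districts >= 4L,
            mean_sample_size >= 10L, communities_per_district >= 1L,
            cell_size > 0, smoothing_radius > 0,
            prevalence_scale > 0, prevalence_scale <= 1,
            flagged_fraction >= 0, flagged_fraction < 1,
            water_fraction >= 0, water_fraction < 0.5)
  structure(
    list(seed = as.integer(seed), grid_rows = as.integer(grid_rows),
         grid_cols = as.integer(grid_cols), cell_size = cell_size,
         n_districts = as.integer(n_districts),
         communities_per_district = as.integer(communities_per_district),
         mean_sample_size = as.integer(mean_sample_size),
         smoothing_radius = smoothing_radius,
         prevalence_scale = prevalence_scale,
         flagged_fraction = flagged_fraction,
         water_fraction = water_fraction,
         effect_params = effect_params),
    class = "pod_synth_config"
  )
}

#' @rdname synthetic_config
#' @export
default_effect_params <- function() {
  c(precipitation = 4.0, elevation = 3.0, evi = 1.5,
    pop_density = 1.2, silt = 1.2, clay = 1.2)
}

# seeded evaluation with RNG kinds pinned for cross-session reproducibility
with_pod_seed <- function(seed, code) {
  withr::with_seed(seed, code,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

scale01 <- function(m) {
  r <- range(m)
  if (r[1] == r[2]) return(m * 0)
  (m - r[1]) / (r[2] - r[1])
}

# separable Gaussian convolution with edge renormalisation
gauss_smooth <- function(m, radius) {
  sd <- radius
  h <- max(1L, ceiling(2 * sd))
  k <- stats::dnorm(-h:h, sd = sd)
  conv_rows <- function(x) {
    acc <- matrix(0, nrow(x), ncol(x))
    wgt <- matrix(0, nrow(x), ncol(x))
    for (s in -h:h) {
      w <- k[s + h + 1]
      src <- seq_len(nrow(x)) + s
      ok <- src >= 1 & src <= nrow(x)
      acc[ok, ] <- acc[ok, ] + w * x[src[ok], , drop = FALSE]
      wgt[ok, ] <- wgt[ok, ] + w
    }
    acc / wgt
  }
  t(conv_rows(t(conv_rows(m))))
}

smooth_noise <- function(nr, nc, radius) gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), radius)

#' Generate the synthetic covariate stack
#'
#' Each covariate is smoothed Gaussian white noise blended with broad
#' cross-grid gradients, so neighbouring cells are correlated and covariates
#' are mutually (but not perfectly) correlated, as real climatic layers are:
#' elevation (0-4,000 m), temperature (lapse-rate derived from elevation),
#' precipitation (200-2,500 mm/yr, partly tied to elevation), EVI (0-0.8),
#' log-normal population density (0-20,000 per km2), compositional soil
#' fractions (silt + clay + sand = 100 exactly), slope (Horn gradient of
#' elevation, degrees) and straight-line distance to water bodies (km).
#' Water cells are excluded from the land mask.
#'
#' @param config a [synthetic_config()].
#' @return a [pod_stack] whose layers are the covariates above plus the land
#'   mask; the water mask used for distances is attached as layer
#'   `water` (categorical).
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "pod_synth_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  rad <- config$smoothing_radius
  with_pod_seed(config$seed, {
    f <- replicate(7, smooth_noise(nr, nc, rad), simplify = FALSE)
    yg <- matrix(rep(seq(0, 1, length.out = nr), nc), nr, nc)
    xg <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)

    # rank-to-quantile (copula-style) marginals: the smoothed fields set the
    # spatial pattern, an explicit right-skewed Beta marginal sets the value
    # distribution - most of the study area is dry lowland, with a solid
    # minority of wet highland where the mapped disease can occur
    to_beta <- function(field, a, b) {
      q <- rank(field, ties.method = "first") / (length(field) + 1)
      matrix(stats::qbeta(q, a, b), nrow(field), ncol(field))
    }
    elev01 <- to_beta(0.65 * scale01(f[[1]]) + 0.35 * yg, 1.2, 2.2)
    elevation <- 4000 * elev01
    precip01 <- to_beta(0.45 * scale01(f[[2]]) + 0.30 * elev01 + 0.25 * xg, 1.3, 2.3)
    precipitation <- 200 + 2300 * precip01
    evi <- 0.8 * to_beta(0.75 * scale01(f[[3]]) + 0.25 * precip01, 1.5, 2.5)
    z <- f[[4]] / stats::sd(f[[4]])
    pop_density <- pmin(exp(log(300) + 1.6 * z), 20000)
    # snap soil fractions to multiples of 1/1024 (exactly representable in
    # binary) so silt + clay + sand closes to 100 without rounding error
    silt <- round(100 * (0.05 + 0.55 * scale01(f[[5]])) * 1024) / 1024
    clay <- round((100 - silt) * (0.10 + 0.60 * scale01(f[[6]])) * 1024) / 1024
    sand <- 100 - silt - clay
    temperature <- 30 - 6.5 * elevation / 1000

    wf <- f[[7]]
    water <- (wf <= stats::quantile(wf, config$water_fraction)) * 1
    land <- 1 - water
  })
  mk <- function(m, kind = "continuous") {
    pod_raster(m, origin_x = 0, origin_y = nr * config$cell_size,
               cell_size = config$cell_size, kind = kind)
  }
  water_r <- mk(water, "categorical")
  land_r <- mk(land, "categorical")
  dist_water <- if (any(water == 1)) distance_to_feature(water_r) else
    mk(matrix(sqrt(nr^2 + nc^2) * config$cell_size, nr, nc))
  slope <- slope_from_elevation(mk(elevation), z_factor = 0.001)
  pod_stack(
    list(
      elevation = mk(elevation), precipitation = mk(precipitation),
      temperature = mk(temperature), evi = mk(evi),
      pop_density = mk(pop_density), silt = mk(silt), clay = mk(clay),
      sand = mk(sand), slope = slope, dist_water = dist_water,
      water = water_r
    ),
    land_mask = land_r
  )
}

# additive logit score of the true suitability surface; shapes follow the
# marginal responses observed for podoconiosis: a precipitation ramp rising
# from ~1,000 mm, an elevation window rising over 1,000-2,000 m and falling
# beyond ~2,800 m, EVI rising to ~0.5 then falling, declining log population
# density (flat above ~10,000 /km2), rising silt, falling clay
suitability_score <- function(df, effect_params = default_effect_params()) {
  p <- effect_params
  # the three main terms are centred at 0.7, not 0.5: absence is the default
  # state and occurrence requires a jointly favourable environment, so most
  # of each covariate's range contributes negatively to the logit
  g_precip <- stats::plogis((df$precipitation - 1000) / 250) - 0.7
  g_elev <- stats::plogis((df$elevation - 1500) / 250) -
    stats::plogis((df$elevation - 3100) / 150) - 0.7
  g_evi <- stats::plogis((df$evi - 0.2) / 0.08) -
    stats::plogis((df$evi - 0.55) / 0.08) - 0.7
  g_pop <- 0.5 - stats::plogis((log10(df$pop_density + 1) - 3) / 0.5)
  g_silt <- stats::plogis((df$silt - 30) / 10) - 0.5
  g_clay <- 0.5 - stats::plogis((df$clay - 35) / 10)
  p[["precipitation"]] * g_precip + p[["elevation"]] * g_elev +
    p[["evi"]] * g_evi + p[["pop_density"]] * g_pop +
    p[["silt"]] * g_silt + p[["clay"]] * g_clay
}

#' True suitability surface of the synthetic study area
#'
#' The probability of occurrence is the logistic of an additive score over
#' the covariates (see [generate_covariates()] for the term shapes). With all
#' magnitudes zero the surface is 0.5 everywhere.
#'
#' @param stack a [pod_stack] containing `precipitation`, `elevation`, `evi`,
#'   `pop_density`, `silt` and `clay`.
#' @param effect_params named term magnitudes (see
#'   [default_effect_params()]).
#' @return a probability [pod_raster] in `[0, 1]`.
#' @export
true_suitability <- function(stack, effect_params = default_effect_params()) {
  need <- c("precipitation", "elevation", "evi", "pop_density", "silt", "clay")
  missing_cov <- setdiff(need, names(stack))
  if (length(missing_cov)) {
    stop("stack is missing covariate(s): ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  df <- lapply(need, function(nm) as.vector(stack[[nm]]$values))
  names(df) <- need
  score <- suitability_score(as.data.frame(df), effect_params)
  tmpl <- stack$land_mask
  pod_raster(matrix(stats::plogis(score), nrow(tmpl$values), ncol(tmpl$values)),
             origin_x = tmpl$origin_x, origin_y = tmpl$origin_y,
             cell_size = tmpl$cell_size)
}

# contiguous rectangular district tiling: rows split into bands (= regions),
# bands split column-wise into districts, exact district count honoured
district_tiling <- function(config) {
  nr <- config$grid_rows; nc <- config$grid_cols; nd <- config$n_districts
  n_bands <- max(1L, round(sqrt(nd * nr / nc)))
  n_bands <- min(n_bands, nd)
  per_band <- rep(nd %/% n_bands, n_bands)
  extra <- nd %% n_bands
  if (extra > 0) per_band[seq_len(extra)] <- per_band[seq_len(extra)] + 1L
  row_breaks <- round(seq(0, nr, length.out = n_bands + 1))
  out <- list(); id <- 0L
  for (b in seq_len(n_bands)) {
    col_breaks <- round(seq(0, nc, length.out = per_band[b] + 1))
    for (j in seq_len(per_band[b])) {
      id <- id + 1L
      out[[id]] <- tibble::tibble(
        district_id = sprintf("D%04d", id),
        region_id = sprintf("R%02d", b),
        row0 = row_breaks[b] + 1L, row1 = row_breaks[b + 1],
        col0 = col_breaks[j] + 1L, col1 = col_breaks[j + 1]
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Sample community prevalence surveys from the true surface
#'
#' Districts are contiguous rectangular blocks tiling the grid (bands of
#' blocks form regions). Per district, `communities_per_district` land cells
#' are sampled; each community examines `n ~ max(10, Poisson(mean))` people
#' and observes `cases ~ Binomial(n, prevalence_scale * truth)` at its cell.
#' A seeded fraction of communities is tagged as historical-survey records
#' inside LF-endemic districts, to exercise the record filter.
#'
#' @param stack a [pod_stack] from [generate_covariates()].
#' @param truth probability [pod_raster] from [true_suitability()].
#' @param config the [synthetic_config()].
#' @return a list of class `pod_survey_sim`: `surveys` (tibble with the
#'   survey CSV schema), `districts` and `regions` (integer-coded
#'   [pod_raster]s), `tiling` (block extents), `district_levels`,
#'   `region_levels`.
#' @export
sample_surveys <- function(stack, truth, config) {
  tv <- truth$values
  stopifnot(all(is.na(tv) | (tv >= 0 & tv <= 1)))
  tiling <- district_tiling(config)
  nr <- config$grid_rows; nc <- config$grid_cols
  land <- stack$land_mask$values == 1
  dist_r <- matrix(NA_real_, nr, nc)
  reg_r <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nrow(tiling))) {
    rows <- tiling$row0[i]:tiling$row1[i]
    cols <- tiling$col0[i]:tiling$col1[i]
    dist_r[rows, cols] <- i
    reg_r[rows, cols] <- as.integer(sub("^R", "", tiling$region_id[i]))
  }

  surveys <- with_pod_seed(config$seed + 1L, {
    recs <- vector("list", nrow(tiling))
    cid <- 0L
    for (i in seq_len(nrow(tiling))) {
      rows <- tiling$row0[i]:tiling$row1[i]
      cols <- tiling$col0[i]:tiling$col1[i]
      block <- expand.grid(row = rows, col = cols)
      ok <- land[cbind(block$row, block$col)]
      cand <- block[ok, , drop = FALSE]
      if (nrow(cand) == 0L) cand <- block
      k <- min(config$communities_per_district, nrow(cand))
      pick <- cand[sample.int(nrow(cand), k), , drop = FALSE]
      n_ex <- pmax(10L, stats::rpois(k, config$mean_sample_size))
      prev <- config$prevalence_scale * tv[cbind(pick$row, pick$col)]
      prev[is.na(prev)] <- 0
      cases <- stats::rbinom(k, n_ex, prev)
      recs[[i]] <- tibble::tibble(
        community_id = sprintf("C%05d", cid + seq_len(k)),
        district_id = tiling$district_id[i],
        region_id = tiling$region_id[i],
        lon = stack$land_mask$origin_x + (pick$col - 0.5) * config$cell_size,
        lat = stack$land_mask$origin_y - (pick$row - 0.5) * config$cell_size,
        n_examined = as.integer(n_ex),
        n_cases = as.integer(cases)
      )
      cid <- cid + k
    }
    out <- dplyr::bind_rows(recs)
    flagged <- stats::runif(nrow(out)) < config$flagged_fraction
    out$source <- ifelse(flagged, "lf_2008_2010", "integrated_2013")
    out$lf_endemic_district <- as.integer(flagged)
    out
  })

  mk <- function(m) pod_raster(m, origin_x = stack$land_mask$origin_x,
                               origin_y = stack$land_mask$origin_y,
                               cell_size = config$cell_size, kind = "categorical")
  structure(
    list(surveys = surveys, districts = mk(dist_r), regions = mk(reg_r),
         tiling = tiling,
         district_levels = tiling$district_id,
         region_levels = unique(tiling$region_id)),
    class = "pod_survey_sim"
  )
}

#' Independent presence/absence records for external validation
#'
#' Emulates historical surveys: presence at a sampled land cell is a
#' Bernoulli draw of observing at least one case among `mean_sample_size`
#' examined at the cell's true prevalence.
#'
#' @inheritParams sample_surveys
#' @param n number of records (default 96).
#' @return tibble with `lon`, `lat`, `presence`, `source_year`.
#' @export
sample_external_records <- function(stack, truth, config, n = 96L) {
  land_cells <- which(stack$land_mask$values == 1)
  nr <- nrow(truth$values)
  with_pod_seed(config$seed + 2L, {
    pick <- sample(land_cells, min(n, length(land_cells)))
    row <- ((pick - 1) %% nr) + 1
    col <- ((pick - 1) %/% nr) + 1
    prev <- config$prevalence_scale * truth$values[cbind(row, col)]
    p_presence <- 1 - (1 - prev)^config$mean_sample_size
    tibble::tibble(
      lon = stack$land_mask$origin_x + (col - 0.5) * config$cell_size,
      lat = stack$land_mask$origin_y - (row - 0.5) * config$cell_size,
      presence = stats::rbinom(length(pick), 1L, p_presence),
      source_year = sample(1969:2012, length(pick), replace = TRUE)
    )
  })
}

#' Per-cell population counts from the density layer
#'
#' @param stack a [pod_stack] with a `pop_density` layer (persons per km2).
#' @return a [pod_raster] of persons per cell.
#' @export
population_raster <- function(stack) {
  g <- stack[["pop_density"]]
  pod_raster(g$values * g$cell_size^2, origin_x = g$origin_x,
             origin_y = g$origin_y, cell_size = g$cell_size)
}

#' Run the full synthetic generator
#'
#' Convenience wrapper producing everything downstream stages consume.
#'
#' @param config a [synthetic_config()].
#' @return a list of class `pod_simulation`: `config`, `stack`, `truth`,
#'   `survey_sim`, `external`, `population`.
#' @export
simulate_study <- function(config = synthetic_config()) {
  stack <- generate_covariates(config)
  truth <- true_suitability(stack, config$effect_params)
  survey_sim <- sample_surveys(stack, truth, config)
  external <- sample_external_records(stack, truth, config)
  structure(
    list(config = config, stack = stack, truth = truth,
         survey_sim = survey_sim, external = external,
         population = population_raster(stack)),
    class = "pod_simulation"
  )
}

#' Write a simulation to disk as plain-text fixtures
#'
#' Writes one ASCII grid per raster (covariates, land mask, truth, district
#' and region rasters, population), the survey and external-validation CSVs,
#' and a GeoJSON FeatureCollection of district block outlines. Reading the
#' files back reproduces the values exactly.
#'
#' @param sim a `pod_simulation` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_fixtures <- function(sim, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory ", dir, call. = FALSE)
  }
  for (nm in names(sim$stack)) {
    write_asc(sim$stack[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  write_asc(sim$stack$land_mask, file.path(dir, "land_mask.asc"))
  write_asc(sim$truth, file.path(dir, "true_suitability.asc"))
  write_asc(sim$survey_sim$districts, file.path(dir, "districts.asc"))
  write_asc(sim$survey_sim$regions, file.path(dir, "regions.asc"))
  write_asc(sim$population, file.path(dir, "population.asc"))
  utils::write.csv(sim$survey_sim$surveys, file.path(dir, "surveys.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$external, file.path(dir, "external_records.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(district_geojson(sim$survey_sim$tiling, sim$stack$land_mask),
             file.path(dir, "districts.geojson"))
  invisible(dir)
}

district_geojson <- function(tiling, tmpl) {
  cs <- tmpl$cell_size
  features <- lapply(seq_len(nrow(tiling)), function(i) {
    x0 <- tmpl$origin_x + (tiling$col0[i] - 1) * cs
    x1 <- tmpl$origin_x + tiling$col1[i] * cs
    y0 <- tmpl$origin_y - tiling$row1[i] * cs
    y1 <- tmpl$origin_y - (tiling$row0[i] - 1) * cs
    list(
      type = "Feature",
      properties = list(district_id = tiling$district_id[i],
                        region_id = tiling$region_id[i]),
      geometry = list(
        type = "Polygon",
        coordinates = list(list(c(x0, y0), c(x1, y0), c(x1, y1),
                                c(x0, y1), c(x0, y0)))
      )
    )
  })
  jsonlite::toJSON(list(type = "FeatureCollection", features = features),
                   auto_unbox = TRUE, digits = NA)
}
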
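#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. Exactly one input mode
#' is supported here: a synthetic study generated from `synthetic`; real
#' rasters and surveys can be staged by placing files with the fixture
#' layout into the run directory and skipping [stage_simulate()].
#'
#' @param synthetic a [synthetic_config()].
#' @param brt shared [brt_params()] for every submodel.
#' @param n_submodels ensemble size (default 120).
#' @param covariates candidate covariate layers entering the collinearity
#'   screen; the default is the standard 8-covariate occurrence model.
#' @param collinearity_threshold |r| above which a covariate pair is
#'   collinear (default 0.7).
#' @param thresholds thresholds for the population-at-risk sensitivity
#'   analysis (default `c(0.3, 0.6)`).
#' @param external_n number of independent validation records to simulate.
#' @param curve_grid grid size for marginal-effect curves.
#' @param base_seed seed for the ensemble bootstrap (recorded in the
#'   manifest).
#' @return an object of class `pod_pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            brt = brt_params(),
                            n_submodels = 120L,
                            covariates = c("precipitation", "elevation",
                                           "pop_density", "evi", "slope",
                                           "dist_water", "silt", "clay"),
                            collinearity_threshold = 0.7,
                            thresholds = c(0.3, 0.6),
                            external_n = 96L,
                            curve_grid = 100L,
                            base_seed = 1L) {
  stopifnot(inherits(synthetic, "pod_synth_config"),
            inherits(brt, "pod_brt_params"),
            n_submodels >= 1L, length(covariates) >= 2L,
            collinearity_threshold > 0, length(thresholds) >= 1L)
  structure(
    list(synthetic = synthetic, brt = brt,
         n_submodels = as.integer(n_submodels),
         covariates = covariates,
         collinearity_threshold = collinearity_threshold,
         thresholds = thresholds, external_n = as.integer(external_n),
         curve_grid = as.integer(curve_grid),
         base_seed = as.integer(base_seed)),
    class = "pod_pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file; top-level keys `synthetic`, `brt` and any scalar
#'   field of `pipeline_config()` override the defaults.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, y$synthetic %||% list())
  brt <- do.call(brt_params, y$brt %||% list())
  rest <- y[setdiff(names(y), c("synthetic", "brt"))]
  do.call(pipeline_config, c(list(synthetic = syn, brt = brt), rest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

read_stack_dir <- function(dir, covariates) {
  mask <- read_asc(file.path(dir, "land_mask.asc"), kind = "categorical")
  grids <- lapply(covariates, function(nm) {
    f <- file.path(dir, paste0(nm, ".asc"))
    if (!file.exists(f)) stop("missing raster: ", f, call. = FALSE)
    read_asc(f)
  })
  names(grids) <- covariates
  pod_stack(grids, mask)
}

#' Pipeline stages
#'
#' Each stage reads its inputs from, and writes its outputs into, a run
#' directory, so stages can be re-run independently. [run_pipeline()] chains
#' them.
#'
#' @param config a [pipeline_config()].
#' @param dir run directory.
#' @return each stage returns its main product invisibly.
#' @name stages
NULL

#' @rdname stages
#' @export
stage_simulate <- function(config, dir) {
  run_stage("simulate", {
    sim <- simulate_study(config$synthetic)
    write_fixtures(sim, dir)
    message("simulate: ", nrow(sim$survey_sim$surveys), " communities in ",
            config$synthetic$n_districts, " districts on a ",
            config$synthetic$grid_rows, "x", config$synthetic$grid_cols, " grid")
    invisible(sim)
  })
}

#' @rdname stages
#' @export
stage_aggregate <- function(config, dir) {
  run_stage("aggregate", {
    surveys <- read_surveys(file.path(dir, "surveys.csv"))
    kept <- filter_records(surveys)
    summaries <- aggregate_district(kept)
    tables <- regional_table(summaries, kept)
    utils::write.csv(summaries, file.path(dir, "district_summaries.csv"),
                     row.names = FALSE, quote = FALSE)
    write_regional_tables(tables, dir)
    message("aggregate: ", nrow(kept), " communities -> ", nrow(summaries),
            " districts (", attr(kept, "n_dropped"), " records dropped)")
    invisible(list(records = kept, summaries = summaries, tables = tables))
  })
}

#' @rdname stages
#' @export
stage_screen <- function(config, dir) {
  run_stage("screen", {
    stack <- read_stack_dir(dir, config$covariates)
    surveys <- filter_records(read_surveys(file.path(dir, "surveys.csv")))
    design <- extract_at_points(stack, surveys, config$covariates)
    design$presence <- as.integer(design$n_cases >= 1L)
    design <- design[design$complete, , drop = FALSE]
    screen <- collinearity_filter(design[config$covariates],
                                  config$collinearity_threshold)
    utils::write.csv(design, file.path(dir, "design_matrix.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(screen$cor_matrix),
                     file.path(dir, "correlation_matrix.csv"),
                     row.names = TRUE, quote = FALSE)
    writeLines(screen$retained, file.path(dir, "retained_covariates.txt"))
    message("screen: ", length(screen$retained), "/", length(config$covariates),
            " covariates retained at |r| <= ", config$collinearity_threshold)
    invisible(screen)
  })
}

#' @rdname stages
#' @export
stage_fit <- function(config, dir) {
  run_stage("fit", {
    design <- utils::read.csv(file.path(dir, "design_matrix.csv"))
    retained <- readLines(file.path(dir, "retained_covariates.txt"))
    ens <- fit_ensemble(design[retained], design$presence, config$brt,
                        n_submodels = config$n_submodels,
                        base_seed = config$base_seed)
    stack <- read_stack_dir(dir, retained)
    maps <- predict_maps(ens, stack)
    write_asc(maps$mean_map, file.path(dir, "suitability_mean.asc"))
    write_asc(maps$q_low_map, file.path(dir, "suitability_q_low.asc"))
    write_asc(maps$q_high_map, file.path(dir, "suitability_q_high.asc"))
    write_asc(maps$uncertainty_map, file.path(dir, "uncertainty.asc"))
    infl <- ensemble_influence(ens)
    utils::write.csv(infl, file.path(dir, "influence.csv"),
                     row.names = FALSE, quote = FALSE)
    curves <- ensemble_marginal_curves(ens, n_grid = config$curve_grid)
    utils::write.csv(curves, file.path(dir, "marginal_curves.csv"),
                     row.names = FALSE, quote = FALSE)
    model_dir <- file.path(dir, "models")
    if (!dir.exists(model_dir)) dir.create(model_dir)
    files <- vapply(seq_along(ens$submodels), function(i) {
      f <- file.path(model_dir, sprintf("submodel_%03d.json", i))
      write_brt(ens$submodels[[i]], f)
      f
    }, character(1))
    manifest <- list(
      base_seed = config$base_seed,
      n_submodels = config$n_submodels,
      params = unclass(config$brt),
      covariates = retained,
      submodels = lapply(seq_along(ens$submodels), function(i) {
        m <- ens$submodels[[i]]
        list(file = basename(files[i]), seed = m$params$seed,
             n_trees = m$n_trees, hash = rlang::hash(m))
      })
    )
    jsonlite::write_json(manifest, file.path(dir, "ensemble_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    message("fit: ", config$n_submodels, " submodels; ", nrow(maps$design),
            " land pixels predicted")
    invisible(list(ensemble = ens, maps = maps, influence = infl,
                   curves = curves))
  })
}

read_ensemble_dir <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "ensemble_manifest.json"),
                                  simplifyVector = TRUE)
  design <- utils::read.csv(file.path(dir, "design_matrix.csv"))
  retained <- readLines(file.path(dir, "retained_covariates.txt"))
  submodels <- lapply(manifest$submodels$file, function(f) {
    read_brt(file.path(dir, "models", f))
  })
  X <- as.matrix(design[retained])
  structure(list(submodels = submodels, X = X, y = design$presence,
                 base_seed = manifest$base_seed,
                 params = do.call(brt_params, as.list(manifest$params))),
            class = "pod_ensemble")
}

#' @rdname stages
#' @export
stage_validate <- function(config, dir) {
  run_stage("validate", {
    ens <- read_ensemble_dir(dir)
    cv <- cross_validate_ensemble(ens)
    mean_map <- read_asc(file.path(dir, "suitability_mean.asc"))
    external <- utils::read.csv(file.path(dir, "external_records.csv"))
    ext <- external_validate(mean_map, external)
    # occurrence threshold from the training sites' ensemble-mean scores
    P <- vapply(ens$submodels, function(m) predict.pod_brt(m, ens$X, "probability"),
                numeric(nrow(ens$X)))
    mean_scores <- rowMeans(P)
    thr <- select_threshold(mean_scores, ens$y)
    utils::write.csv(cv$per_submodel, file.path(dir, "cross_validation.csv"),
                     row.names = FALSE, quote = FALSE)
    report <- list(
      optimal_threshold = as.list(thr),
      cross_validation = cv$summary,
      external = list(auc = ext$auc, band = ext$band, n_used = ext$n_used)
    )
    jsonlite::write_json(report, file.path(dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    message(sprintf(
      "validate: cv AUC %.3f, external AUC %.3f (%s), threshold %.3f",
      cv$summary$mean[cv$summary$statistic == "auc"], ext$auc, ext$band,
      thr$threshold))
    invisible(list(cv = cv, external = ext, threshold = thr))
  })
}

#' @rdname stages
#' @param tau occurrence threshold; defaults to the optimum recorded by
#'   [stage_validate()].
#' @export
stage_limits <- function(config, dir, tau = NULL) {
  run_stage("limits", {
    if (is.null(tau)) {
      rep <- jsonlite::read_json(file.path(dir, "validation.json"),
                                 simplifyVector = TRUE)
      tau <- rep$optimal_threshold$threshold
    }
    maps <- list(
      mean_map = read_asc(file.path(dir, "suitability_mean.asc")),
      q_low_map = read_asc(file.path(dir, "suitability_q_low.asc")),
      q_high_map = read_asc(file.path(dir, "suitability_q_high.asc"))
    )
    lim <- occurrence_limits(maps, tau)
    write_asc(lim$mean_limits, file.path(dir, "limits_mean.asc"))
    write_asc(lim$low_limits, file.path(dir, "limits_low.asc"))
    write_asc(lim$high_limits, file.path(dir, "limits_high.asc"))
    message(sprintf("limits: binarized at tau = %.4f", tau))
    invisible(lim)
  })
}

#' @rdname stages
#' @export
stage_risk <- function(config, dir) {
  run_stage("risk", {
    rep <- jsonlite::read_json(file.path(dir, "validation.json"),
                               simplifyVector = TRUE)
    tau <- rep$optimal_threshold$threshold
    maps <- list(
      mean_map = read_asc(file.path(dir, "suitability_mean.asc")),
      q_low_map = read_asc(file.path(dir, "suitability_q_low.asc")),
      q_high_map = read_asc(file.path(dir, "suitability_q_high.asc"))
    )
    population <- read_asc(file.path(dir, "population.asc"))
    zones <- read_asc(file.path(dir, "regions.asc"), kind = "categorical")
    risk <- population_at_risk(occurrence_limits(maps, tau), population, zones)
    sens <- threshold_sensitivity(maps, population, zones,
                                  sort(unique(c(config$thresholds, tau))))
    utils::write.csv(risk, file.path(dir, "risk_table.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(sens, file.path(dir, "threshold_sensitivity.csv"),
                     row.names = FALSE, quote = FALSE)
    tot <- risk[risk$zone == "Total", ]
    message(sprintf(
      "risk: %.0f persons (%.1f%%) inside the limits at tau = %.4f",
      tot$population_at_risk, tot$percent_exposed, tau))
    invisible(list(risk = risk, sensitivity = sens))
  })
}

#' Run the full pipeline
#'
#' simulate -> aggregate -> screen -> fit -> validate -> limits -> risk,
#' writing every artefact (survey tables, screen report, ensemble maps,
#' influence and marginal-effect tables, validation report, binary limits,
#' risk tables, sensitivity analysis and a manifest) into `dir`. Rerunning
#' with the same configuration reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param dir output directory (created if needed).
#' @return a list with the main in-memory products of each stage, invisibly.
#' @export
run_pipeline <- function(config, dir) {
  stopifnot(inherits(config, "pod_pipeline_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- stage_simulate(config, dir)
  agg <- stage_aggregate(config, dir)
  screen <- stage_screen(config, dir)
  fit <- stage_fit(config, dir)
  val <- stage_validate(config, dir)
  lim <- stage_limits(config, dir)
  risk <- stage_risk(config, dir)
  manifest <- list(
    package = "podomap",
    version = as.character(utils::packageVersion("podomap")),
    config = config_as_list(config),
    config_hash = rlang::hash(config_as_list(config)),
    seeds = list(synthetic = config$synthetic$seed,
                 brt = config$brt$seed,
                 ensemble_base = config$base_seed)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(sim = sim, aggregate = agg, screen = screen, fit = fit,
                 validation = val, limits = lim, risk = risk))
}

config_as_list <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else unclass(x)
  }
  strip(config)
}
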
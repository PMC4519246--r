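# shared fixtures, built in code

# a tiny aligned stack: 4x4, all land, two named layers
tiny_stack <- function() {
  mask <- pod_raster(matrix(1, 4, 4), cell_size = 1, kind = "categorical")
  a <- pod_raster(matrix(as.numeric(1:16), 4, 4), cell_size = 1)
  b <- pod_raster(matrix(as.numeric(16:1), 4, 4), cell_size = 1)
  pod_stack(list(a = a, b = b), mask)
}

# hand-built community records
toy_records <- function() {
  tibble::tibble(
    community_id = sprintf("C%02d", 1:5),
    district_id = c("D1", "D1", "D2", "D2", "D3"),
    region_id = c("R1", "R1", "R1", "R2", "R2"),
    lon = c(0.5, 1.5, 2.5, 3.5, 0.5),
    lat = c(0.5, 0.5, 1.5, 1.5, 2.5),
    n_examined = c(50L, 150L, 100L, 80L, 120L),
    n_cases = c(3L, 1L, 0L, 4L, 0L),
    source = c("integrated_2013", "integrated_2013", "lf_2008_2010",
               "lf_2008_2010", "integrated_2013"),
    lf_endemic_district = c(0L, 0L, 1L, 0L, 0L)
  )
}

# regional totals of the 2013 national integrated lymphoedema mapping survey
# (districts, clusters, examined, cases) - used as printed-table inputs
national_regional_counts <- function() {
  tibble::tribble(
    ~region, ~districts, ~clusters, ~examined, ~cases, ~prev_2dp, ~ci_low, ~ci_high,
    "Addis Ababa", 4L, 8L, 800L, 0L, 0.00, NA, NA,
    "Affar", 32L, 64L, 6257L, 0L, 0.00, NA, NA,
    "Amhara", 144L, 285L, 28170L, 1097L, 3.89, 3.67, 4.12,
    "Benishangul Gumuz", 20L, 21L, 1737L, 8L, 0.46, 0.14, 0.78,
    "DireDawa", 7L, 14L, 1400L, 0L, 0.00, NA, NA,
    "Gambella", 11L, 16L, 819L, 0L, 0.00, NA, NA,
    "Harari", 9L, 18L, 1801L, 1L, 0.06, NA, NA,  # printed CI not reproducible
    "Oromia", 298L, 541L, 53647L, 2158L, 4.02, 3.86, 4.19,
    "SNNPR", 155L, 285L, 27860L, 2404L, 8.63, 8.30, 8.96,
    "Somali", 49L, 99L, 9583L, 14L, 0.15, 0.07, 0.22,
    "Tigray", 46L, 91L, 9164L, 30L, 0.33, 0.21, 0.44
  )
}

# per-region district counts by prevalence category from the same survey
national_category_counts <- function() {
  tibble::tribble(
    ~region, ~zero, ~gt0_le1, ~gt1_le5, ~gt5_le10, ~gt10_le15, ~gt15,
    "Addis Ababa", 4L, 0L, 0L, 0L, 0L, 0L,
    "Affar", 32L, 0L, 0L, 0L, 0L, 0L,
    "Amhara", 55L, 25L, 40L, 6L, 7L, 11L,
    "Benishangul Gumuz", 16L, 1L, 3L, 1L, 0L, 0L,
    "Dire Dawa", 7L, 0L, 0L, 0L, 0L, 0L,
    "Gambella", 10L, 0L, 0L, 0L, 0L, 0L,
    "Harari", 8L, 1L, 0L, 0L, 0L, 0L,
    "Oromia", 104L, 50L, 76L, 32L, 15L, 21L,
    "SNNPR", 21L, 6L, 39L, 40L, 24L, 25L,
    "Somali", 38L, 10L, 1L, 0L, 0L, 0L,
    "Tigray", 30L, 12L, 4L, 0L, 0L, 0L
  )
}

# expand per-region category counts into one synthetic district summary per
# district, with a representative prevalence inside each bin
expand_category_counts <- function(counts) {
  rep_prev <- c(zero = 0, gt0_le1 = 0.5, gt1_le5 = 3, gt5_le10 = 7,
                gt10_le15 = 12, gt15 = 20)
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    for (cat in names(rep_prev)) {
      k <- counts[[cat]][i]
      if (k > 0) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          region_id = counts$region[i],
          prevalence_pct = rep(rep_prev[[cat]], k)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  n <- 1000L
  out$district_id <- sprintf("D%04d", seq_len(nrow(out)))
  out$n_communities <- 2L
  out$n_examined <- n
  out$n_cases <- as.integer(round(out$prevalence_pct / 100 * n))
  out$prevalence_pct <- 100 * out$n_cases / out$n_examined
  out$presence <- out$n_cases >= 1L
  out$category <- classify_prevalence(out$prevalence_pct)
  out
}

# small seeded synthetic simulation shared by slower tests
small_sim <- function(seed = 11, rows = 48, cols = 48, districts = 32) {
  suppressMessages(simulate_study(synthetic_config(
    seed = seed, grid_rows = rows, grid_cols = cols, n_districts = districts
  )))
}

model_covariates <- function() {
  c("precipitation", "elevation", "pop_density", "evi", "slope",
    "dist_water", "silt", "clay")
}

# community design matrix + presence labels from a simulation
sim_design <- function(sim) {
  recs <- suppressMessages(filter_records(sim$survey_sim$surveys))
  des <- extract_at_points(sim$stack, recs, model_covariates())
  des <- des[des$complete, , drop = FALSE]
  des$presence <- as.integer(des$n_cases >= 1L)
  des
}
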
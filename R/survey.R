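#' Read community survey records
#'
#' Reads the survey CSV (columns `community_id`, `district_id`, `region_id`,
#' `lon`, `lat`, `n_examined`, `n_cases`, `source`, `lf_endemic_district`)
#' and validates record-level invariants.
#'
#' @param path CSV file path.
#' @return a validated tibble of community records.
#' @export
read_surveys <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_surveys(df)
}

#' @rdname read_surveys
#' @param records a data frame of community records.
#' @export
validate_surveys <- function(records) {
  need <- c("community_id", "district_id", "region_id", "lon", "lat",
            "n_examined", "n_cases", "source", "lf_endemic_district")
  missing_col <- setdiff(need, names(records))
  if (length(missing_col)) {
    stop("survey records are missing column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  bad_source <- setdiff(unique(records$source), c("integrated_2013", "lf_2008_2010"))
  if (length(bad_source)) {
    stop("invalid source value(s): ", paste(bad_source, collapse = ", "),
         call. = FALSE)
  }
  with(records, {
    if (any(n_examined <= 0)) stop("n_examined must be positive", call. = FALSE)
    if (any(n_cases < 0 | n_cases > n_examined)) {
      stop("n_cases must lie in [0, n_examined]", call. = FALSE)
    }
    if (any(!is.finite(lon) | !is.finite(lat))) {
      stop("coordinates must be finite", call. = FALSE)
    }
  })
  tibble::as_tibble(records)
}

#' Exclude historical records from LF-endemic districts
#'
#' Drops records sourced from the historical (2008-2010) survey that sit in
#' districts endemic for lymphatic filariasis, where lymphoedema cannot be
#' attributed to podoconiosis without misclassification risk. All other
#' records are retained.
#'
#' @param records a validated tibble of community records.
#' @return the retained records; the number dropped is attached as attribute
#'   `n_dropped` and reported by message.
#' @export
filter_records <- function(records) {
  records <- validate_surveys(records)
  drop <- records$source == "lf_2008_2010" & records$lf_endemic_district == 1
  out <- records[!drop, , drop = FALSE]
  message(sum(drop), " record(s) dropped (historical survey in LF-endemic district), ",
          nrow(out), " retained")
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Binomial confidence interval for a prevalence, in percent
#'
#' Normal approximation on the proportion, `p +/- z * sqrt(p(1-p)/n)`,
#' expressed in percent and clamped to `[0, 100]`. Vectorised.
#'
#' @param n_cases,n_examined case and examination counts.
#' @param level confidence level in (0, 1); default 0.95.
#' @return a tibble with columns `low_pct`, `high_pct`.
#' @export
prevalence_ci <- function(n_cases, n_examined, level = 0.95) {
  if (length(level) != 1L || !is.finite(level) || level <= 0 || level >= 1) {
    stop("`level` must be a single number in (0, 1)", call. = FALSE)
  }
  stopifnot(all(n_examined >= 1), all(n_cases >= 0), all(n_cases <= n_examined))
  p <- n_cases / n_examined
  z <- stats::qnorm((1 + level) / 2)
  half <- z * sqrt(p * (1 - p) / n_examined)
  tibble::tibble(
    low_pct = pmax(0, 100 * (p - half)),
    high_pct = pmin(100, 100 * (p + half))
  )
}

prevalence_categories <- c("zero", "gt0_le1", "gt1_le5", "gt5_le10",
                           "gt10_le15", "gt15")

#' Classify a district prevalence into reporting bins
#'
#' `zero` iff exactly 0; otherwise the half-open bins (0,1], (1,5], (5,10],
#' (10,15], (15,100] on the unrounded percent prevalence (printed bin labels
#' like "0.01-1" are display artefacts of 2-dp rounding).
#'
#' @param prevalence_pct prevalence in percent, in `[0, 100]`. Vectorised.
#' @return a factor with levels `zero`, `gt0_le1`, `gt1_le5`, `gt5_le10`,
#'   `gt10_le15`, `gt15`.
#' @export
classify_prevalence <- function(prevalence_pct) {
  if (any(prevalence_pct < 0 | prevalence_pct > 100)) {
    stop("prevalence must lie in [0, 100]", call. = FALSE)
  }
  cut(prevalence_pct, breaks = c(-Inf, 0, 1, 5, 10, 15, 100),
      labels = prevalence_categories, right = TRUE)
}

#' Aggregate community records to district summaries
#'
#' Pools examined and case counts over the communities of each district and
#' derives prevalence, its confidence interval, the presence/absence label
#' (at least one case in the district) and the prevalence category.
#'
#' @param records filtered community records.
#' @param level confidence level for the prevalence interval.
#' @return a tibble of district summaries, one row per district.
#' @export
aggregate_district <- function(records, level = 0.95) {
  records <- validate_surveys(records)
  dup <- records |>
    dplyr::count(.data$district_id, .data$community_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop("duplicate community_id within district(s): ",
         paste(unique(dup$district_id), collapse = ", "), call. = FALSE)
  }
  out <- records |>
    dplyr::group_by(.data$district_id, .data$region_id) |>
    dplyr::summarise(
      n_communities = dplyr::n(),
      n_examined = sum(.data$n_examined),
      n_cases = sum(.data$n_cases),
      .groups = "drop"
    ) |>
    dplyr::mutate(prevalence_pct = 100 * .data$n_cases / .data$n_examined)
  ci <- prevalence_ci(out$n_cases, out$n_examined, level)
  out |>
    dplyr::mutate(
      ci_low_pct = ci$low_pct,
      ci_high_pct = ci$high_pct,
      presence = .data$n_cases >= 1L,
      category = classify_prevalence(.data$prevalence_pct)
    )
}

#' Regional prevalence and category tables
#'
#' Builds the two standard national summary tables from district summaries:
#' a per-region prevalence table (districts, clusters, population surveyed,
#' cases, prevalence with CI) and a per-region count of districts by
#' prevalence category (plus `n_le1`/`n_gt1` splits), each with a `Total`
#' row that equals the column sums. Also reports the share of surveyed
#' districts with no cases.
#'
#' @param summaries district summaries from [aggregate_district()].
#' @param records the community records the summaries were built from (used
#'   for cluster counts).
#' @param level confidence level for prevalence intervals.
#' @return a list of class `pod_regional_table`: `prevalence` (tibble),
#'   `categories` (tibble), `zero_share_pct` (percent of districts with
#'   presence = FALSE).
#' @export
regional_table <- function(summaries, records, level = 0.95) {
  reg <- summaries |>
    dplyr::group_by(region_id = .data$region_id) |>
    dplyr::summarise(
      districts = dplyr::n(),
      clusters = sum(.data$n_communities),
      n_examined = sum(.data$n_examined),
      n_cases = sum(.data$n_cases),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$region_id)
  total <- reg |>
    dplyr::summarise(
      region_id = "Total",
      districts = sum(.data$districts), clusters = sum(.data$clusters),
      n_examined = sum(.data$n_examined), n_cases = sum(.data$n_cases)
    )
  prev_tab <- dplyr::bind_rows(reg, total) |>
    dplyr::mutate(prevalence_pct = 100 * .data$n_cases / .data$n_examined)
  ci <- prevalence_ci(prev_tab$n_cases, prev_tab$n_examined, level)
  prev_tab$ci_low_pct <- ci$low_pct
  prev_tab$ci_high_pct <- ci$high_pct

  cat_counts <- summaries |>
    dplyr::count(region_id = .data$region_id, category = .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L,
                       names_expand = TRUE) |>
    dplyr::arrange(.data$region_id)
  for (lv in prevalence_categories) {
    if (!lv %in% names(cat_counts)) cat_counts[[lv]] <- 0L
  }
  cat_counts <- cat_counts[, c("region_id", prevalence_categories)]
  cat_counts <- cat_counts |>
    dplyr::mutate(
      total = rowSums(dplyr::across(dplyr::all_of(prevalence_categories))),
      n_le1 = .data$zero + .data$gt0_le1,
      n_gt1 = .data$total - .data$n_le1
    )
  cat_total <- cat_counts |>
    dplyr::summarise(dplyr::across(-"region_id", sum)) |>
    dplyr::mutate(region_id = "Total", .before = 1L)
  cat_tab <- dplyr::bind_rows(cat_counts, cat_total)

  structure(
    list(
      prevalence = prev_tab,
      categories = cat_tab,
      zero_share_pct = 100 * sum(!summaries$presence) / nrow(summaries)
    ),
    class = "pod_regional_table"
  )
}

#' @export
print.pod_regional_table <- function(x, ...) {
  cat("<pod_regional_table>\n")
  cat(sprintf("  %d regions; %.1f%% of districts with no cases\n",
              nrow(x$prevalence) - 1L, x$zero_share_pct))
  print(x$prevalence, n = Inf)
  invisible(x)
}

#' Write regional tables as CSV
#'
#' @param tables a `pod_regional_table`.
#' @param dir output directory.
#' @return paths written, invisibly.
#' @export
write_regional_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "regional_prevalence.csv")
  p2 <- file.path(dir, "regional_categories.csv")
  utils::write.csv(tables$prevalence, p1, row.names = FALSE, quote = FALSE)
  utils::write.csv(tables$categories, p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}
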
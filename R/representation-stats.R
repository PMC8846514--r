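#' Tabulate records at a chosen level
#'
#' Counts always partition the input records. Country- and region-level
#' tables include an `Unknown` row for records whose location did not
#' resolve (plus, at region level, Antarctica). The body-site table counts
#' every sample but only resolved countries in its `countries` column.
#'
#' @param records records tibble after [attribute_geography()].
#' @param level one of `"country"`, `"region"`, `"body_site"`,
#'   `"body_site_country"`, `"year_region"`.
#' @return A counts tibble; shape depends on `level`.
#' @export
tabulate_samples <- function(records,
                             level = c("country", "region", "body_site",
                                       "body_site_country", "year_region")) {
  level <- match.arg(level)
  if (nrow(records) == 0) {
    return(switch(level,
      country = ,
      region = tibble::tibble(unit = character(), samples = integer()),
      body_site = tibble::tibble(body_site = character(),
                                 samples = integer(), countries = integer()),
      body_site_country = tibble::tibble(body_site = character(),
                                         unit = character(),
                                         samples = integer()),
      year_region = tibble::tibble(year = integer(), region = character(),
                                   samples = integer())))
  }
  country_unit <- ifelse(records$geo_status == "resolved",
                         records$country_name, "Unknown")
  switch(level,
    country = count_units(country_unit),
    region = count_units(records$region),
    body_site = records |>
      dplyr::group_by(body_site = .data$body_site) |>
      dplyr::summarise(
        samples = dplyr::n(),
        countries = dplyr::n_distinct(
          .data$country_code[.data$geo_status == "resolved"]),
        .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$samples)),
    body_site_country = tibble::tibble(body_site = records$body_site,
                                       unit = country_unit) |>
      dplyr::count(.data$body_site, .data$unit, name = "samples") |>
      dplyr::arrange(.data$body_site, dplyr::desc(.data$samples)),
    year_region = tibble::tibble(
      year = as.integer(format(records$release_date, "%Y")),
      region = records$region) |>
      dplyr::count(.data$year, .data$region, name = "samples") |>
      dplyr::arrange(.data$year, .data$region)
  )
}

count_units <- function(unit) {
  tab <- sort(table(unit), decreasing = TRUE)
  tibble::tibble(unit = names(tab), samples = as.integer(tab))
}

#' Add sample-share columns to a counts table
#'
#' `share_all` divides by the full cohort size (Unknown included);
#' `share_known` divides by the located total and is `NA` for the Unknown
#' row. Rounding happens only at the presentation layer.
#'
#' @param counts tibble with columns `unit`, `samples`.
#' @param total_all total number of samples (defaults to `sum(samples)`).
#' @param total_known located-sample total (defaults to the sum excluding
#'   the `Unknown` unit).
#' @return `counts` plus `share_all`, `share_known`.
#' @export
shares <- function(counts, total_all = sum(counts$samples),
                   total_known = sum(counts$samples[counts$unit != "Unknown"])) {
  if (total_all <= 0 || total_known <= 0) {
    stop_geosample("share totals must be positive", "geosample_input_error")
  }
  counts$share_all <- counts$samples / total_all
  counts$share_known <- ifelse(counts$unit == "Unknown", NA_real_,
                               counts$samples / total_known)
  counts
}

#' Representation proportion of a unit
#'
#' A unit's share of located samples divided by its share of world
#' population; 1 means exactly proportional representation.
#'
#' @param share_known fraction of located samples (> 0).
#' @param pop_share fraction of world population (> 0).
#' @return `share_known / pop_share`.
#' @export
representation_proportion <- function(share_known, pop_share) {
  if (any(pop_share <= 0, na.rm = TRUE)) {
    stop_geosample("population share must be positive",
                   "geosample_input_error")
  }
  if (any(share_known <= 0, na.rm = TRUE)) {
    stop_geosample(
      "representation proportion is undefined for units without samples",
      "geosample_input_error")
  }
  share_known / pop_share
}

#' Signed raw representation index
#'
#' For a unit with at least its proportional share of samples, the ratio
#' `sample_pct / pop_pct` (>= 1, positive = overrepresented). For a unit
#' with fewer, the negative reciprocal `-(pop_pct / sample_pct)`, whose
#' magnitude is the factor by which its sample count would have to grow to
#' reach proportionality. Exact proportionality lands on the positive
#' branch with value 1. Units with zero samples return `NA` (the no-samples
#' sentinel, mapped separately on choropleths).
#'
#' @param sample_pct,pop_pct percentage (or fraction) pairs on a common
#'   scale; `pop_pct` must be positive, `sample_pct` non-negative.
#' @return Signed numeric vector with `NA` for zero-sample units.
#' @export
raw_index <- function(sample_pct, pop_pct) {
  if (any(sample_pct < 0, na.rm = TRUE) || any(pop_pct <= 0, na.rm = TRUE)) {
    stop_geosample("shares must be non-negative (population share positive)",
                   "geosample_input_error")
  }
  ifelse(is.na(sample_pct) | sample_pct == 0, NA_real_,
         ifelse(sample_pct >= pop_pct,
                sample_pct / pop_pct,
                -(pop_pct / sample_pct)))
}

#' Build a representation table from counts and populations
#'
#' Convenience wrapper chaining [shares()], [representation_proportion()],
#' and [raw_index()] over a table of per-unit sample counts and
#' populations. Units without a population (e.g. an `Unknown` row) keep
#' their sample counts and `share_all` but get `NA` statistics; they are
#' excluded from the located-sample and world-population denominators.
#'
#' @param counts tibble with columns `unit`, `samples`,
#'   `population_thousands` (`NA` allowed for Unknown-style rows).
#' @param total_all denominator for `share_all`; defaults to
#'   `sum(samples)`.
#' @return Tibble with `share_all`, `share_known`, `pop_share`,
#'   `repr_proportion`, `raw_index` columns added.
#' @export
representation_table <- function(counts, total_all = sum(counts$samples)) {
  known <- !is.na(counts$population_thousands) & counts$unit != "Unknown"
  total_known <- sum(counts$samples[known])
  world_pop <- sum(counts$population_thousands[known])
  if (total_known <= 0 || world_pop <= 0) {
    stop_geosample("need at least one located unit with positive population",
                   "geosample_input_error")
  }
  counts$share_all <- counts$samples / total_all
  counts$share_known <- ifelse(known, counts$samples / total_known, NA_real_)
  counts$pop_share <- ifelse(known,
                             counts$population_thousands / world_pop,
                             NA_real_)
  counts$repr_proportion <- ifelse(
    known & counts$samples > 0,
    counts$share_known / counts$pop_share, NA_real_)
  counts$raw_index <- NA_real_
  counts$raw_index[known] <- raw_index(100 * counts$share_known[known],
                                       100 * counts$pop_share[known])
  counts
}

#' Scale signed indices onto the ±100 display range
#'
#' Units with `min_samples` or fewer samples are excluded ("50 or fewer"
#' is inclusive). Positive scores are min-max scaled onto (0, 100] by
#' `x -> 100 * x / max(x)`; negative scores independently onto [-100, 0)
#' by `x -> -100 * |x| / max(|x|)`; both anchor 0 at exact
#' proportionality, so within-sign ordering and signs are preserved.
#'
#' @param rows tibble with columns `samples`, `raw_index`.
#' @param min_samples exclusive lower bound on sample count (default 50).
#' @return `rows` plus `scaled_index` and `index_note`
#'   (`ok | excluded_low_n | no_samples`).
#' @export
scale_indices <- function(rows, min_samples = 50) {
  no_samples <- is.na(rows$raw_index)
  excluded <- !no_samples & rows$samples <= min_samples
  ok <- !no_samples & !excluded
  rows$index_note <- ifelse(no_samples, "no_samples",
                            ifelse(excluded, "excluded_low_n", "ok"))
  rows$scaled_index <- NA_real_
  pos <- ok & rows$raw_index > 0
  neg <- ok & rows$raw_index < 0
  if (any(pos)) {
    rows$scaled_index[pos] <- 100 * rows$raw_index[pos] / max(rows$raw_index[pos])
  }
  if (any(neg)) {
    rows$scaled_index[neg] <- -100 * abs(rows$raw_index[neg]) /
      max(abs(rows$raw_index[neg]))
  }
  if (!any(ok)) {
    warning("all units excluded from index scaling", call. = FALSE)
  }
  rows
}

#' Sign-preserving log transform for choropleth coloring
#'
#' `sign(x) * log10(1 + |x|)`: monotone, maps 0 to 0, and spreads the
#' middling scores that a linear ±100 scale would crowd together.
#'
#' @param scaled_index numeric vector in \[-100, 100\].
#' @return Transformed values.
#' @export
display_transform <- function(scaled_index) {
  sign(scaled_index) * log10(1 + abs(scaled_index))
}

#' Annual and cumulative sample counts per region
#'
#' @param records records tibble with release dates and regions.
#' @return Tibble (`year`, `region`, `samples_released`,
#'   `cumulative_samples`, `annual_share`) on the complete year x region
#'   grid spanning the observed years; cumulative counts are nondecreasing
#'   per region and annual shares sum to 1 within each year that has
#'   samples.
#' @export
time_series <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(year = integer(), region = character(),
                          samples_released = integer(),
                          cumulative_samples = integer(),
                          annual_share = double()))
  }
  year <- as.integer(format(records$release_date, "%Y"))
  grid <- tidyr::expand_grid(
    year = seq(min(year), max(year)),
    region = sort(unique(records$region)))
  counted <- tibble::tibble(year = year, region = records$region) |>
    dplyr::count(.data$year, .data$region, name = "samples_released")
  grid |>
    dplyr::left_join(counted, by = c("year", "region")) |>
    dplyr::mutate(samples_released =
                    tidyr::replace_na(.data$samples_released, 0L)) |>
    dplyr::group_by(.data$region) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::mutate(cumulative_samples = cumsum(.data$samples_released)) |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(annual_share = if (sum(.data$samples_released) > 0) {
      .data$samples_released / sum(.data$samples_released)
    } else NA_real_) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$year, .data$region)
}
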
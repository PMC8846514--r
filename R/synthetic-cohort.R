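#' Default generative mixtures for synthetic cohorts
#'
#' The default country, body-site, and year mixtures emulate the composition
#' of the public human-microbiome sample pool as of a mid-2021 repository
#' snapshot: country mass concentrated in the United States and a tail of
#' high-income countries, body-site mass dominated by gut samples, and
#' release years growing roughly geometrically from 2010 to 2020.
#'
#' @name cohort_defaults
#' @keywords internal
NULL

default_country_weights <- function() {
  counts <- c(
    USA = 178960, CHN = 36162, GBR = 16076, DNK = 11497, AUS = 9266,
    NLD = 9173, CAN = 8829, FIN = 7855, ITA = 6265, DEU = 5531,
    ESP = 5517, SWE = 5248, ISR = 4831, NZL = 4354, JPN = 4298,
    CHL = 3616, BGD = 3502, FRA = 3402, MWI = 3052, IND = 2997,
    # tail mass spread across the remaining regions
    BRA = 5228, ZAF = 5228, MEX = 5228, RUS = 5228, KOR = 5228,
    THA = 5228, PAK = 5228, NGA = 5228, PER = 5228, TZA = 5228
  )
  counts / sum(counts)
}

default_body_site_weights <- function() {
  counts <- c(
    "Gut" = 220017, "Human metagenome" = 69697, "Oral" = 47798,
    "Skin" = 36593, "Vaginal" = 17784, "Lung" = 17307,
    "Nasopharyngeal" = 15646, "Feces" = 6858, "Reproductive system" = 3180,
    "Blood" = 2707, "Saliva" = 2503, "Milk" = 2060, "Urinary tract" = 1187,
    "Tracheal" = 520, "Sputum" = 364, "Eye" = 359, "Semen" = 203,
    "Bile" = 45, "Skeleton" = 1
  )
  counts / sum(counts)
}

default_year_weights <- function() {
  w <- 1.4^(0:10)
  stats::setNames(w / sum(w), 2010:2020)
}

#' Configure a synthetic metadata cohort
#'
#' Builds and validates the generative parameters for
#' [generate_cohort()]. All probability maps must sum to 1 (within 1e-9)
#' and all probabilities lie in \[0, 1\].
#'
#' @param n_samples number of records to generate (>= 1).
#' @param country_weights named probability vector over ISO-3166 alpha-3
#'   codes from the world table.
#' @param body_site_weights named probability vector over body-site labels.
#' @param p_generic_category probability a record is filed under the generic
#'   (non-human-labeled) taxonomy category of its body site, when one
#'   exists.
#' @param p_human_host_given_generic probability a generic-category record
#'   carries a host value indicating a human.
#' @param p_geo_missing probability the geographic attribute is absent or a
#'   null token.
#' @param p_geo_messy probability a known country is written as a
#'   nonstandard synonym, upper-cased name, or "Country: subdivision"
#'   string.
#' @param p_no_runs probability a record has zero linked sequencing runs.
#' @param year_weights named probability vector over release years.
#' @param seed integer RNG seed; a fixed seed yields byte-identical output.
#' @param null_tokens vocabulary used for explicit-null geography values.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples,
                          country_weights = default_country_weights(),
                          body_site_weights = default_body_site_weights(),
                          p_generic_category = 0.29,
                          p_human_host_given_generic = 0.173,
                          p_geo_missing = 0.14,
                          p_geo_messy = 0.2,
                          p_no_runs = 0.02,
                          year_weights = default_year_weights(),
                          seed = 1L,
                          null_tokens = default_null_tokens()) {
  cfg <- list(
    n_samples = n_samples, country_weights = country_weights,
    body_site_weights = body_site_weights,
    p_generic_category = p_generic_category,
    p_human_host_given_generic = p_human_host_given_generic,
    p_geo_missing = p_geo_missing, p_geo_messy = p_geo_messy,
    p_no_runs = p_no_runs, year_weights = year_weights,
    seed = as.integer(seed), null_tokens = null_tokens
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  bad_field <- function(field, msg) {
    stop_geosample(sprintf("invalid cohort config field '%s': %s", field, msg),
                   "geosample_config_error")
  }
  if (length(cfg$n_samples) != 1 || is.na(cfg$n_samples) ||
      cfg$n_samples < 1 || cfg$n_samples != floor(cfg$n_samples)) {
    bad_field("n_samples", "must be a positive integer")
  }
  for (field in c("country_weights", "body_site_weights", "year_weights")) {
    w <- cfg[[field]]
    if (is.null(names(w)) || any(names(w) == "")) {
      bad_field(field, "must be a named probability vector")
    }
    if (any(w < 0 | w > 1)) bad_field(field, "probabilities outside [0, 1]")
    if (abs(sum(w) - 1) > 1e-9) {
      bad_field(field, sprintf("probabilities sum to %.12f, not 1", sum(w)))
    }
  }
  for (field in c("p_generic_category", "p_human_host_given_generic",
                  "p_geo_missing", "p_geo_messy", "p_no_runs")) {
    p <- cfg[[field]]
    if (length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      bad_field(field, "must be a single probability in [0, 1]")
    }
  }
  invisible(cfg)
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_cohort_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic BioSample-style cohort with known ground truth
#'
#' Draws `n_samples` metadata records field-by-field in a fixed order from
#' one seeded generator, so a fixed seed reproduces the cohort exactly.
#' Every record carries the latent truth it was drawn from, aggregated into
#' marginal tables, so downstream pipeline stages can be tested against an
#' exact answer.
#'
#' @param config a [cohort_config()].
#' @param body_sites body-site taxonomy table ([load_body_site_table()]).
#' @param world world reference table ([load_world_table()]).
#' @return A list with elements:
#'   \describe{
#'     \item{records}{tibble of sample records (`accession`,
#'       `taxonomy_id`, `release_date`, `attributes` list-column).}
#'     \item{runs}{RunInfo-style tibble (`Run`, `BioSample`,
#'       `LibraryStrategy`, `ReleaseDate`).}
#'     \item{truth}{ground truth: `by_country` (codes plus "Unknown"),
#'       `by_body_site`, `by_year` marginals over all records; per-stage
#'       survivor counts `n_samples`, `n_with_runs`, `n_dated_pre_cutoff`,
#'       `n_in_scope` (default pipeline parameters); `attribute_usage`;
#'       and the per-record `latent` tibble.}
#'   }
#' @export
generate_cohort <- function(config,
                            body_sites = load_body_site_table(),
                            world = load_world_table()) {
  validate_cohort_config(config)
  unknown <- setdiff(names(config$country_weights), world$country_code)
  if (length(unknown) > 0) {
    stop_geosample(paste0("invalid cohort config field 'country_weights': ",
                          "codes not in world table: ",
                          paste(unknown, collapse = ", ")),
                   "geosample_config_error")
  }
  unknown_site <- setdiff(names(config$body_site_weights), body_sites$body_site)
  if (length(unknown_site) > 0) {
    stop_geosample(paste0("invalid cohort config field 'body_site_weights': ",
                          "labels not in body-site table: ",
                          paste(unknown_site, collapse = ", ")),
                   "geosample_config_error")
  }
  n <- as.integer(config$n_samples)
  site_tbl <- body_sites

  draws <- with_cohort_seed(config$seed, {
    country <- sample(names(config$country_weights), n, replace = TRUE,
                      prob = config$country_weights)
    body_site <- sample(names(config$body_site_weights), n, replace = TRUE,
                        prob = config$body_site_weights)
    has_generic <- !is.na(site_tbl$generic_taxid[
      match(body_site, site_tbl$body_site)])
    is_generic <- stats::runif(n) < config$p_generic_category & has_generic
    human_host <- is_generic &
      stats::runif(n) < config$p_human_host_given_generic
    geo_missing <- stats::runif(n) < config$p_geo_missing
    geo_messy <- !geo_missing & stats::runif(n) < config$p_geo_messy
    messy_style <- sample.int(3L, n, replace = TRUE)
    null_absent <- stats::runif(n) < 0.5
    explicit_nulls <- setdiff(config$null_tokens, "")
    null_token <- sample(explicit_nulls, n, replace = TRUE)
    no_runs <- stats::runif(n) < config$p_no_runs
    n_runs <- ifelse(no_runs, 0L, 1L + stats::rpois(n, 0.6))
    year <- as.integer(sample(names(config$year_weights), n, replace = TRUE,
                              prob = config$year_weights))
    doy <- sample.int(365L, n, replace = TRUE) - 1L
    host_style <- sample.int(6L, n, replace = TRUE)
    strategies <- sample(c("AMPLICON", "WGS"), sum(n_runs), replace = TRUE,
                         prob = c(0.72, 0.28))
    list(country = country, body_site = body_site, is_generic = is_generic,
         human_host = human_host, geo_missing = geo_missing,
         geo_messy = geo_messy, messy_style = messy_style,
         null_absent = null_absent, null_token = null_token,
         n_runs = n_runs, year = year, doy = doy, host_style = host_style,
         strategies = strategies)
  })

  accession <- sprintf("SAMN%08d", seq_len(n))
  site_idx <- match(draws$body_site, site_tbl$body_site)
  taxonomy_id <- ifelse(draws$is_generic,
                        site_tbl$generic_taxid[site_idx],
                        site_tbl$human_taxid[site_idx])
  release_date <- as.Date(sprintf("%d-01-01", draws$year)) + draws$doy

  country_name <- world$country_name[match(draws$country, world$country_code)]
  geo_value <- country_name
  messy1 <- draws$country                       # bare ISO-3166 code
  messy2 <- toupper(country_name)               # shouty spelling
  messy3 <- paste0(country_name, ": Region ", (seq_len(n) %% 5) + 1)
  geo_value[draws$geo_messy & draws$messy_style == 1] <-
    messy1[draws$geo_messy & draws$messy_style == 1]
  geo_value[draws$geo_messy & draws$messy_style == 2] <-
    messy2[draws$geo_messy & draws$messy_style == 2]
  geo_value[draws$geo_messy & draws$messy_style == 3] <-
    messy3[draws$geo_messy & draws$messy_style == 3]
  geo_value[draws$geo_missing] <- draws$null_token[draws$geo_missing]
  geo_present <- !(draws$geo_missing & draws$null_absent)

  human_host_values <- c("9606", "Homo sapiens", "human", "human adult",
                         "patient", "volunteer")
  other_host_values <- c("Mus musculus", "mouse", "Sus scrofa", "bovine",
                         "Canis lupus familiaris", "environmental")
  host_value <- ifelse(draws$human_host,
                       human_host_values[draws$host_style],
                       other_host_values[draws$host_style])
  host_is_taxid <- draws$human_host & draws$host_style == 1

  attributes <- vector("list", n)
  for (i in seq_len(n)) {
    attrs <- c(collection_date = format(release_date[i]))
    if (geo_present[i]) attrs <- c(attrs, geo_loc_name = geo_value[i])
    if (draws$is_generic[i]) {
      if (host_is_taxid[i]) {
        attrs <- c(attrs, host_taxid = host_value[i])
      } else {
        attrs <- c(attrs, host = host_value[i])
      }
    }
    attributes[[i]] <- attrs
  }

  records <- tibble::tibble(
    accession = accession,
    taxonomy_id = as.integer(taxonomy_id),
    release_date = release_date,
    attributes = attributes
  )

  run_sample <- rep(accession, draws$n_runs)
  runs <- tibble::tibble(
    Run = sprintf("SRR%08d", seq_along(run_sample)),
    BioSample = run_sample,
    LibraryStrategy = draws$strategies,
    ReleaseDate = format(rep(release_date, draws$n_runs))
  )

  truth <- cohort_truth(draws, accession, site_tbl, config)
  list(records = records, runs = runs, truth = truth)
}

# Ground truth computed directly from the latent draws (never through the
# pipeline under test).
cohort_truth <- function(draws, accession, site_tbl, config) {
  n <- length(accession)
  cutoff <- as.Date("2021-01-01")
  release_date <- as.Date(sprintf("%d-01-01", draws$year)) + draws$doy
  true_country <- ifelse(draws$geo_missing, "Unknown", draws$country)

  survives_runs <- draws$n_runs > 0
  survives_date <- survives_runs & release_date < cutoff

  # scoping truth under default pipeline parameters (threshold 1000 applied
  # to realized generic-category counts among records reaching that stage)
  generic_taxid <- site_tbl$generic_taxid[
    match(draws$body_site, site_tbl$body_site)]
  generic_counts <- table(generic_taxid[draws$is_generic & survives_date])
  admitted <- as.integer(names(generic_counts)[generic_counts >= 1000])
  in_scope <- survives_date &
    (!draws$is_generic |
       (draws$human_host & generic_taxid %in% admitted))

  att_geo <- sum(!draws$geo_missing)
  att_host_taxid <- sum(draws$is_generic & draws$human_host &
                          draws$host_style == 1)
  att_host <- sum(draws$is_generic) - att_host_taxid
  usage <- tibble::tibble(
    attribute = c("collection_date", "geo_loc_name", "host", "host_taxid"),
    samples = c(n, att_geo, att_host, att_host_taxid)
  )
  usage <- usage[usage$samples > 0, ]

  list(
    by_country = sort(table(true_country), decreasing = TRUE),
    by_body_site = sort(table(draws$body_site), decreasing = TRUE),
    by_year = table(draws$year),
    n_samples = n,
    n_with_runs = sum(survives_runs),
    n_dated_pre_cutoff = sum(survives_date),
    n_in_scope = sum(in_scope),
    admitted_generic_taxids = admitted,
    attribute_usage = usage,
    latent = tibble::tibble(
      accession = accession,
      country_code = ifelse(draws$geo_missing, NA_character_, draws$country),
      body_site = draws$body_site,
      is_generic = draws$is_generic,
      human_host = draws$human_host,
      geo_missing = draws$geo_missing,
      n_runs = draws$n_runs,
      year = draws$year,
      in_scope = in_scope
    )
  )
}
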
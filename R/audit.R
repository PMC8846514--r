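#' Configure an end-to-end audit run
#'
#' Collects input paths, reference-table paths, and pipeline parameters,
#' and validates that every referenced file exists before any stage runs.
#'
#' @param xml one or more BioSample XML (or JSON) input paths.
#' @param runinfo RunInfo-style CSV path.
#' @param out_dir output directory for report tables and the manifest.
#' @param world,gazetteer,body_sites,lexicon reference-table paths
#'   (defaults: the packaged tables).
#' @param generic_threshold generic-category admission threshold.
#' @param min_samples low-count exclusion bound for index scaling.
#' @param cutoff release-date cutoff (exclusive).
#' @param count_null_as_present attribute-usage policy flag.
#' @return An `audit_config` list.
#' @export
audit_config <- function(xml, runinfo, out_dir,
                         world = geosample_extdata("world_countries.csv"),
                         gazetteer = geosample_extdata("gazetteer.csv"),
                         body_sites = geosample_extdata("body_sites.csv"),
                         lexicon = geosample_extdata("host_lexicon.yml"),
                         generic_threshold = 1000,
                         min_samples = 50,
                         cutoff = as.Date("2021-01-01"),
                         count_null_as_present = FALSE) {
  cfg <- list(xml = xml, runinfo = runinfo, out_dir = out_dir,
              world = world, gazetteer = gazetteer,
              body_sites = body_sites, lexicon = lexicon,
              generic_threshold = generic_threshold,
              min_samples = min_samples, cutoff = as.Date(cutoff),
              count_null_as_present = count_null_as_present)
  class(cfg) <- "audit_config"
  missing <- c(cfg$xml, cfg$runinfo, cfg$world, cfg$gazetteer,
               cfg$body_sites, cfg$lexicon)
  missing <- missing[!file.exists(missing)]
  if (length(missing) > 0) {
    stop_geosample(paste0("audit config references missing file(s): ",
                          paste(missing, collapse = ", ")),
                   "geosample_config_error")
  }
  if (cfg$generic_threshold <= 0 || cfg$min_samples <= 0) {
    stop_geosample("thresholds must be positive", "geosample_config_error")
  }
  cfg
}

#' Run the full representation audit
#'
#' Executes ingest -> scope -> geolocate -> stats, writes the report tables
#' (per-country, per-body-site, per-region with representation statistics,
#' body-site x country cross-tab, time series, attribute usage) as CSV,
#' and a JSON run manifest recording record counts entering and leaving
#' every stage, the parameters used, and checksums of the reference
#' tables. Any stage error aborts with the stage name; nothing is written
#' unless every stage succeeds.
#'
#' @param config an [audit_config()].
#' @return Invisibly, a list with all report tables and the manifest.
#' @export
run_audit <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_geosample(sprintf("audit stage '%s' failed: %s", name,
                             conditionMessage(e)),
                     "geosample_pipeline_error")
    })
  }

  world <- stage("validate", load_world_table(config$world))
  gazetteer <- stage("validate", load_gazetteer(config$gazetteer, world))
  body_sites <- stage("validate", load_body_site_table(config$body_sites))
  lexicon <- stage("validate", load_host_lexicon(config$lexicon))
  stage("validate", validate_references(world, gazetteer, body_sites, lexicon))

  records <- stage("ingest", {
    parsed <- lapply(config$xml, parse_biosample)
    all <- dplyr::bind_rows(parsed)
    dup <- unique(all$accession[duplicated(all$accession)])
    if (length(dup) > 0) {
      stop_geosample(paste0("duplicate accessions across inputs: ",
                            paste(dup, collapse = ", ")),
                     "geosample_parse_error")
    }
    all
  })
  n_parsed <- nrow(records)

  records <- stage("ingest", link_runs(records, read_runinfo(config$runinfo)))
  records <- stage("ingest", filter_sequenced(records))
  n_unsequenced <- attr(records, "n_removed")
  records <- stage("ingest", filter_release_date(records, config$cutoff))
  n_undated <- attr(records, "n_removed_undated")
  n_late <- attr(records, "n_removed_late")
  n_ingested <- nrow(records)

  usage <- stage("ingest",
                 attribute_usage(records, config$count_null_as_present))

  scoped <- stage("scope", scope_records(records, body_sites, lexicon,
                                         config$generic_threshold))
  located <- stage("geolocate",
                   attribute_geography(scoped$records, world, gazetteer))
  records <- located$records

  tables <- stage("stats", {
    country_counts <- tabulate_samples(records, "country")
    country_tbl <- shares(country_counts)
    region_counts <- tabulate_samples(records, "region")
    region_pop <- tibble::tibble(
      unit = region_counts$unit,
      samples = region_counts$samples,
      population_thousands = vapply(region_counts$unit, function(r) {
        if (r == "Unknown") NA_real_
        else sum(world$population_thousands[world$sdg_region == r])
      }, double(1)))
    region_tbl <- representation_table(region_pop)
    country_pop <- tibble::tibble(
      unit = country_counts$unit,
      samples = country_counts$samples,
      population_thousands = world$population_thousands[
        match(country_counts$unit, world$country_name)])
    country_repr <- scale_indices(representation_table(country_pop),
                                  config$min_samples)
    country_repr$display_value <- display_transform(country_repr$scaled_index)
    list(
      country = country_tbl,
      body_site = tabulate_samples(records, "body_site"),
      region = region_tbl,
      country_representation = country_repr,
      body_site_country = tabulate_samples(records, "body_site_country"),
      time_series = time_series(records),
      attribute_usage = usage
    )
  })

  manifest <- list(
    parameters = list(
      generic_threshold = config$generic_threshold,
      min_samples = config$min_samples,
      cutoff = format(config$cutoff),
      count_null_as_present = config$count_null_as_present
    ),
    stages = list(
      parsed = n_parsed,
      removed_no_runs = n_unsequenced,
      removed_missing_date = n_undated,
      removed_after_cutoff = n_late,
      ingested = n_ingested,
      scoped = scoped$report$n_retained,
      located = located$report$by_status[["resolved"]]
    ),
    scope_report = scoped$report[c("n_input", "n_human_labeled",
                                   "n_generic_evaluated",
                                   "distinct_host_values",
                                   "n_values_flagged", "n_records_flagged",
                                   "flagged_pct", "n_retained")],
    geo_report = located$report[c("by_status", "n_distinct_countries",
                                  "known_share")],
    reference_checksums = as.list(tools::md5sum(
      c(world = config$world, gazetteer = config$gazetteer,
        body_sites = config$body_sites, lexicon = config$lexicon)))
  )

  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  written <- character()
  tryCatch({
    out <- function(name) file.path(config$out_dir, name)
    files <- c(country = "samples_per_country.csv",
               body_site = "samples_per_body_site.csv",
               region = "region_representation.csv",
               country_representation = "country_representation.csv",
               body_site_country = "samples_per_body_site_per_country.csv",
               time_series = "time_series.csv",
               attribute_usage = "attribute_usage.csv")
    for (key in names(files)) {
      readr::write_csv(tables[[key]], out(files[[key]]))
      written <- c(written, out(files[[key]]))
    }
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    written <- c(written, out("manifest.json"))
  }, error = function(e) {
    unlink(written)
    stop_geosample(paste0("audit stage 'write' failed: ",
                          conditionMessage(e)),
                   "geosample_pipeline_error")
  })

  invisible(c(tables, list(manifest = manifest)))
}
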
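#' Path to a packaged reference table
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @export
geosample_extdata <- function(file = NULL) {
  dir <- system.file("extdata", package = "geosample")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    stop_geosample(sprintf("no packaged reference file '%s'", file),
                   "geosample_reference_error")
  }
  path
}

#' Load the world reference table
#'
#' One row per country or territory in the UN population framework:
#' ISO-3166 alpha-3 code, canonical name, 2020 population estimate in
#' thousands, UN SDG region (one of 8), and least-developed-country flag.
#' Antarctica is deliberately not a row (it has no permanent population and
#' belongs to no SDG region); [resolve_country()] handles it specially.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return Tibble with columns `country_code`, `country_name`,
#'   `population_thousands`, `sdg_region`, `is_ldc`.
#' @export
load_world_table <- function(path = geosample_extdata("world_countries.csv")) {
  world <- readr::read_csv(path, col_types = readr::cols(
    country_code = readr::col_character(),
    country_name = readr::col_character(),
    population_thousands = readr::col_double(),
    sdg_region = readr::col_character(),
    is_ldc = readr::col_logical()
  ))
  check_world_table(world)
  world
}

check_world_table <- function(world) {
  dup <- world$country_code[duplicated(world$country_code)]
  if (length(dup) > 0) {
    stop_geosample(paste0("duplicate country codes: ",
                          paste(unique(dup), collapse = ", ")),
                   "geosample_reference_error")
  }
  bad_pop <- world$country_code[is.na(world$population_thousands) |
                                  world$population_thousands <= 0]
  if (length(bad_pop) > 0) {
    stop_geosample(paste0("non-positive population for: ",
                          paste(bad_pop, collapse = ", ")),
                   "geosample_reference_error")
  }
  regions <- sort(unique(world$sdg_region))
  if (length(regions) != 8) {
    stop_geosample(sprintf("expected exactly 8 SDG regions, found %d: %s",
                           length(regions), paste(regions, collapse = "; ")),
                   "geosample_reference_error")
  }
  invisible(world)
}

#' Load the country-name gazetteer
#'
#' Maps alias spellings ("USA", "United States of America", "Viet Nam", ...)
#' to ISO-3166 alpha-3 codes. The lookup index built from it also covers
#' every canonical name and code in the world table, so the canonical
#' spelling of each country always resolves.
#'
#' @param path CSV path with columns `alias`, `country_code`; defaults to the
#'   packaged gazetteer.
#' @param world world table the aliases must point into.
#' @return Tibble with columns `alias`, `country_code`.
#' @export
load_gazetteer <- function(path = geosample_extdata("gazetteer.csv"),
                           world = load_world_table()) {
  gaz <- readr::read_csv(path, col_types = readr::cols(
    alias = readr::col_character(),
    country_code = readr::col_character()
  ))
  check_gazetteer(gaz, world)
  gaz
}

check_gazetteer <- function(gaz, world) {
  key <- fold_key(gaz$alias)
  conflicts <- stats::aggregate(gaz$country_code, list(key = key),
                                function(v) length(unique(v)))
  bad <- conflicts$key[conflicts$x > 1]
  if (length(bad) > 0) {
    stop_geosample(paste0("alias mapped to more than one country code: ",
                          paste(bad, collapse = ", ")),
                   "geosample_reference_error")
  }
  unknown <- setdiff(unique(gaz$country_code),
                     c(world$country_code, "ATA"))
  if (length(unknown) > 0) {
    stop_geosample(paste0("gazetteer points at unknown country codes: ",
                          paste(unknown, collapse = ", ")),
                   "geosample_reference_error")
  }
  invisible(gaz)
}

# Folded-alias -> code named vector; includes canonical names, codes,
# aliases, and the Antarctica special entry.
build_geo_index <- function(world, gazetteer) {
  keys <- c(fold_key(world$country_name), fold_key(world$country_code),
            fold_key(gazetteer$alias), "antarctica")
  vals <- c(world$country_code, world$country_code,
            gazetteer$country_code, "ATA")
  keep <- !duplicated(keys)
  idx <- vals[keep]
  names(idx) <- keys[keep]
  idx
}

#' Load the body-site taxonomy table
#'
#' Maps NCBI-taxonomy metagenome categories to the 19 body-site labels used
#' in human-microbiome audits. Each row carries the taxid of the
#' human-labeled category (e.g. "human gut metagenome", 408170) and, where
#' one exists, the taxid of the corresponding generic category (e.g. "gut
#' metagenome") that can hold samples from any host species. The packaged
#' table anchors the well-known IDs (gut 408170/749906, the body-site-less
#' "human metagenome" 646099) and is an editable configuration input: IDs
#' for the rarer categories should be checked against the NCBI Taxonomy
#' Browser before a live harvest.
#'
#' @param path CSV path with columns `body_site`, `human_taxid`,
#'   `generic_taxid`; defaults to the packaged table.
#' @return Tibble with those columns.
#' @export
load_body_site_table <- function(path = geosample_extdata("body_sites.csv")) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    body_site = readr::col_character(),
    human_taxid = readr::col_integer(),
    generic_taxid = readr::col_integer()
  ), na = "NA")
  check_body_site_table(tbl)
  tbl
}

check_body_site_table <- function(tbl) {
  dup_site <- tbl$body_site[duplicated(tbl$body_site)]
  if (length(dup_site) > 0) {
    stop_geosample(paste0("duplicate body-site labels: ",
                          paste(dup_site, collapse = ", ")),
                   "geosample_reference_error")
  }
  ids <- c(tbl$human_taxid, tbl$generic_taxid)
  ids <- ids[!is.na(ids)]
  dup_id <- ids[duplicated(ids)]
  if (length(dup_id) > 0) {
    stop_geosample(paste0("taxid assigned to more than one category: ",
                          paste(dup_id, collapse = ", ")),
                   "geosample_reference_error")
  }
  if (!any(tbl$human_taxid == 408170 & tolower(tbl$body_site) == "gut")) {
    stop_geosample("body-site table must contain the gut anchor row (408170)",
                   "geosample_reference_error")
  }
  invisible(tbl)
}

#' Load the human-host lexicon
#'
#' Token lists used to decide whether a free-text host value on a
#' generic-category record indicates a human host: taxids accepted as
#' human, positive substrings ("human", "patient", ...), and negative
#' overrides naming other species that veto a match.
#'
#' @param path YAML path; defaults to the packaged lexicon.
#' @return List with elements `human_taxids` (integer vector),
#'   `positive_tokens`, `negative_overrides` (lowercase character vectors).
#' @export
load_host_lexicon <- function(path = geosample_extdata("host_lexicon.yml")) {
  lex <- yaml::read_yaml(path)
  lex$human_taxids <- as.integer(lex$human_taxids)
  lex$positive_tokens <- tolower(lex$positive_tokens)
  lex$negative_overrides <- tolower(lex$negative_overrides)
  check_host_lexicon(lex)
  lex
}

check_host_lexicon <- function(lex) {
  overlap <- intersect(lex$positive_tokens, lex$negative_overrides)
  if (length(overlap) > 0) {
    stop_geosample(paste0("tokens listed as both positive and negative: ",
                          paste(overlap, collapse = ", ")),
                   "geosample_reference_error")
  }
  invisible(lex)
}

#' Load the attribute-name alias table
#'
#' Harmonizes alternative spellings of metadata attribute names (e.g.
#' "geographic location" vs "geo_loc_name") onto canonical names during
#' parsing.
#'
#' @param path CSV path with columns `alias`, `canonical`.
#' @return Named character vector mapping folded alias -> canonical name.
#' @export
load_attribute_aliases <- function(path = geosample_extdata("attribute_aliases.csv")) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    alias = readr::col_character(),
    canonical = readr::col_character()
  ))
  stats::setNames(tbl$canonical, fold_key(tbl$alias))
}

#' Validate all reference tables at once
#'
#' Runs every structural invariant check on the world table, gazetteer,
#' body-site table, and host lexicon, failing fast with row-level
#' diagnostics. [run_audit()] calls this before any pipeline stage runs.
#'
#' @param world,gazetteer,body_sites,lexicon loaded reference objects; by
#'   default the packaged ones.
#' @return Invisibly, a tibble with one row per check (`check`, `status`).
#' @export
validate_references <- function(world = load_world_table(),
                                gazetteer = load_gazetteer(world = world),
                                body_sites = load_body_site_table(),
                                lexicon = load_host_lexicon()) {
  check_world_table(world)
  check_gazetteer(gazetteer, world)
  check_body_site_table(body_sites)
  check_host_lexicon(lexicon)
  # totality: every world row reachable by at least its canonical name
  idx <- build_geo_index(world, gazetteer)
  hit <- idx[fold_key(world$country_name)]
  missed <- world$country_name[is.na(hit) | hit != world$country_code]
  if (length(missed) > 0) {
    stop_geosample(paste0("canonical names shadowed in the gazetteer index: ",
                          paste(missed, collapse = ", ")),
                   "geosample_reference_error")
  }
  invisible(tibble::tibble(
    check = c("world_table", "gazetteer", "body_sites", "host_lexicon",
              "gazetteer_totality"),
    status = "ok"
  ))
}
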
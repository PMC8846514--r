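# Hand-built records tibble for unit fixtures.
make_records <- function(accession, taxonomy_id = 408170,
                         release_date = as.Date("2020-06-01"),
                         attributes = NULL) {
  n <- length(accession)
  if (is.null(attributes)) attributes <- rep(list(character()), n)
  tibble::tibble(
    accession = accession,
    taxonomy_id = rep_len(as.integer(taxonomy_id), n),
    release_date = rep_len(as.Date(release_date), n),
    attributes = attributes
  )
}

# Records already geo-attributed, for stats fixtures.
make_located <- function(country_name, region = NA_character_,
                         body_site = "Gut",
                         release_date = as.Date("2020-06-01")) {
  n <- length(country_name)
  resolved <- !is.na(country_name) & country_name != "Unknown"
  tibble::tibble(
    accession = sprintf("SAMN%03d", seq_len(n)),
    taxonomy_id = 408170L,
    release_date = rep_len(as.Date(release_date), n),
    attributes = rep(list(character()), n),
    body_site = rep_len(body_site, n),
    country_code = ifelse(resolved, substr(toupper(country_name), 1, 3), NA),
    country_name = ifelse(resolved, country_name, NA),
    region = ifelse(is.na(region), "Unknown", region),
    is_ldc = FALSE,
    geo_status = ifelse(resolved, "resolved", "absent")
  )
}

# Cached reference tables so tests do not reload CSVs repeatedly.
ref_world <- load_world_table()
ref_gazetteer <- load_gazetteer(world = ref_world)
ref_body_sites <- load_body_site_table()
ref_lexicon <- load_host_lexicon()
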
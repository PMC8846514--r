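#' Attribute names searched for geographic origin, in priority order
#' @return Character vector of attribute names.
#' @export
default_geo_attributes <- function() {
  c("geo_loc_name", "geographic location (country and/or sea)",
    "geographic location")
}

#' Split a raw geographic value into country token and subdivision
#'
#' INSDC convention writes sample origin as `"Country: subdivision"`; the
#' value is split on the first colon and both parts trimmed. Explicit null
#' tokens give status `"null_token"`; empty or absent values give
#' `"absent"`; everything else is a `"candidate"` for gazetteer lookup.
#'
#' @param raw character vector of raw values (may contain `NA`).
#' @param null_tokens null vocabulary.
#' @return Tibble (`country_token`, `subdivision`, `status`).
#' @export
parse_geo_value <- function(raw, null_tokens = default_null_tokens()) {
  n <- length(raw)
  country <- rep(NA_character_, n)
  subdivision <- rep(NA_character_, n)
  status <- rep("candidate", n)

  absent <- is.na(raw) | trimws(raw) == ""
  status[absent] <- "absent"
  nulls <- !absent & is_null_token(raw, null_tokens)
  status[nulls] <- "null_token"

  cand <- !absent & !nulls
  if (any(cand)) {
    parts <- regmatches(raw[cand], regexpr(":", raw[cand]), invert = TRUE)
    country[cand] <- trimws(vapply(parts, `[`, character(1), 1))
    sub <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                  character(1))
    subdivision[cand] <- trimws(sub)
  }
  tibble::tibble(country_token = country, subdivision = subdivision,
                 status = status)
}

#' Resolve country tokens against the gazetteer
#'
#' Exact lookup after case, whitespace, and diacritic folding. Antarctica
#' resolves to the code `ATA` but carries region `"Unknown"` (it belongs to
#' no SDG region). Unmatched tokens get status `"unrecognized"` and are
#' counted under Unknown downstream; ambiguous historical names are left
#' unrecognized rather than guessed.
#'
#' @param token character vector of country tokens.
#' @param world world reference table.
#' @param gazetteer alias table.
#' @return Tibble (`country_code`, `country_name`, `region`, `is_ldc`,
#'   `status`) aligned with `token`.
#' @export
resolve_country <- function(token, world = load_world_table(),
                            gazetteer = load_gazetteer(world = world)) {
  idx <- build_geo_index(world, gazetteer)
  code <- unname(idx[fold_key(token)])
  code[is.na(token)] <- NA_character_

  wi <- match(code, world$country_code)
  out <- tibble::tibble(
    country_code = code,
    country_name = world$country_name[wi],
    region = world$sdg_region[wi],
    is_ldc = world$is_ldc[wi],
    status = ifelse(is.na(code), "unrecognized", "resolved")
  )
  ata <- !is.na(code) & code == "ATA"
  out$country_name[ata] <- "Antarctica"
  out$region[ata] <- "Unknown"
  out$is_ldc[ata] <- FALSE
  out$region[out$status != "resolved"] <- "Unknown"
  out$is_ldc[out$status != "resolved"] <- FALSE
  out
}

#' Attach a geographic assignment to every record
#'
#' Reads the first available geographic attribute in priority order, parses
#' it, and resolves it to a country, SDG region, and LDC flag. Every record
#' ends up with a `geo_status` in `resolved | null_token | unrecognized |
#' absent`, and the four statuses partition the cohort.
#'
#' @param records records tibble (after scoping).
#' @param world world reference table.
#' @param gazetteer alias table.
#' @param geo_attributes attribute names to search, in priority order.
#' @param null_tokens null vocabulary.
#' @return List with `records` (plus columns `geo_raw`, `country_code`,
#'   `country_name`, `region`, `is_ldc`, `geo_status`) and `report`
#'   (counts by status, `n_distinct_countries`, `known_share`).
#' @export
attribute_geography <- function(records, world = load_world_table(),
                                gazetteer = load_gazetteer(world = world),
                                geo_attributes = default_geo_attributes(),
                                null_tokens = default_null_tokens()) {
  raw <- vapply(records$attributes, function(attrs) {
    for (a in geo_attributes) {
      v <- attr_get(attrs, a)
      if (!is.na(v)) return(v)
    }
    NA_character_
  }, character(1))

  parsed <- parse_geo_value(raw, null_tokens)
  resolved <- resolve_country(parsed$country_token, world, gazetteer)

  status <- parsed$status
  cand <- status == "candidate"
  status[cand] <- resolved$status[cand]

  records$geo_raw <- raw
  records$country_code <- ifelse(cand, resolved$country_code, NA_character_)
  records$country_name <- ifelse(cand, resolved$country_name, NA_character_)
  records$region <- ifelse(cand, resolved$region, "Unknown")
  records$is_ldc <- ifelse(cand, resolved$is_ldc, FALSE)
  records$geo_status <- status

  counts <- table(factor(status, levels = c("resolved", "null_token",
                                            "unrecognized", "absent")))
  report <- list(
    n_records = nrow(records),
    by_status = stats::setNames(as.integer(counts), names(counts)),
    n_distinct_countries = length(unique(stats::na.omit(records$country_code))),
    known_share = if (nrow(records) > 0) {
      as.integer(counts[["resolved"]]) / nrow(records)
    } else NA_real_
  )
  list(records = records, report = report)
}
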
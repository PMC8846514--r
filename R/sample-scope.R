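#' Classify taxonomy IDs into body sites
#'
#' A taxid matching a human-labeled category maps to that body site with
#' origin `"human-labeled"`; a taxid matching a generic category maps with
#' origin `"generic"`; anything else is out of scope (`NA`).
#'
#' @param taxonomy_id integer vector of NCBI taxids.
#' @param table body-site taxonomy table ([load_body_site_table()]).
#' @return Tibble (`body_site`, `origin`) aligned with `taxonomy_id`.
#' @export
classify_body_site <- function(taxonomy_id, table = load_body_site_table()) {
  hi <- match(taxonomy_id, table$human_taxid)
  gi <- match(taxonomy_id, table$generic_taxid)
  body_site <- ifelse(!is.na(hi), table$body_site[hi],
                      ifelse(!is.na(gi), table$body_site[gi], NA_character_))
  origin <- ifelse(!is.na(hi), "human-labeled",
                   ifelse(!is.na(gi), "generic", NA_character_))
  tibble::tibble(body_site = body_site, origin = origin)
}

#' Admit generic categories by sample count
#'
#' Generic metagenome categories (which can hold samples from any host
#' species) are only screened for human hosts when they are large enough to
#' be worth it: a category is admitted when it holds at least `threshold`
#' samples (inclusive).
#'
#' @param per_category_counts named integer vector, names = generic taxids.
#' @param threshold inclusive minimum count (default 1000).
#' @return Integer vector of admitted generic taxids.
#' @export
select_generic_categories <- function(per_category_counts, threshold = 1000) {
  if (length(per_category_counts) == 0) return(integer())
  if (any(per_category_counts < 0)) {
    stop_geosample("negative category counts", "geosample_input_error")
  }
  as.integer(names(per_category_counts)[per_category_counts >= threshold])
}

#' Derive the putative host value of a record
#'
#' The `host_taxid` attribute takes precedence; when it is absent or a null
#' token, the `host` attribute is used; when both are absent the result is
#' `NA`.
#'
#' @param attributes a single named character vector of attributes, or the
#'   `attributes` list-column of a records tibble.
#' @param null_tokens null vocabulary.
#' @return Character vector of putative host values (`NA` where none).
#' @export
derive_putative_host <- function(attributes,
                                 null_tokens = default_null_tokens()) {
  if (!is.list(attributes)) attributes <- list(attributes)
  vapply(attributes, function(attrs) {
    taxid <- attr_get(attrs, "host_taxid")
    if (!is.na(taxid) && !is_null_token(taxid, null_tokens)) return(taxid)
    host <- attr_get(attrs, "host")
    if (!is.na(host) && !is_null_token(host, null_tokens)) return(host)
    NA_character_
  }, character(1))
}

#' Decide whether a host value indicates a human
#'
#' A value counts as human when it parses to a taxid in the lexicon's
#' `human_taxids`, or when it case-insensitively contains a positive token
#' ("human", "patient", ...) and no negative override (another species
#' name). `NA` values are never human.
#'
#' @param value character vector of putative host values.
#' @param lexicon host lexicon ([load_host_lexicon()]).
#' @return Logical vector.
#' @export
flag_human_host <- function(value, lexicon = load_host_lexicon()) {
  out <- logical(length(value))
  parsed <- suppressWarnings(as.integer(value))
  numeric_like <- !is.na(parsed) & grepl("^\\s*\\d+\\s*$", value)
  out[numeric_like] <- parsed[numeric_like] %in% lexicon$human_taxids
  txt_idx <- which(!numeric_like & !is.na(value))
  if (length(txt_idx) > 0) {
    low <- tolower(value[txt_idx])
    has_any <- function(tokens) {
      Reduce(`|`, lapply(tokens, function(tok) grepl(tok, low, fixed = TRUE)),
             accumulate = FALSE, init = rep(FALSE, length(low)))
    }
    vetoed <- has_any(lexicon$negative_overrides)
    positive <- has_any(lexicon$positive_tokens)
    out[txt_idx] <- positive & !vetoed
  }
  out
}

#' Percentage of evaluated records flagged as human-hosted
#'
#' Presentation-layer arithmetic of the scoping report: flagged records
#' over evaluated records, as a percentage rounded half-away-from-zero to
#' one decimal place.
#'
#' @param n_flagged,n_evaluated integer counts.
#' @return Percentage at 1 dp (`NA` when nothing was evaluated).
#' @export
flagging_rate <- function(n_flagged, n_evaluated) {
  if (n_evaluated <= 0) return(NA_real_)
  round_half_up(100 * n_flagged / n_evaluated, 1)
}

#' Restrict records to the human-microbiome scope
#'
#' Keeps the union of (a) records filed under a human-labeled body-site
#' category and (b) records in admitted generic categories whose putative
#' host value is flagged as human. Every retained record gets `body_site`
#' and `origin` columns. A scoping report summarizes the host screening for
#' audit.
#'
#' @param records records tibble (after the ingest filters).
#' @param table body-site taxonomy table.
#' @param lexicon host lexicon.
#' @param threshold inclusive generic-category admission threshold.
#' @param null_tokens null vocabulary for host derivation.
#' @return List with `records` (retained, with `body_site`/`origin`) and
#'   `report`: `n_input`, `n_human_labeled`, `n_generic_evaluated` (records
#'   in admitted generic categories), `distinct_host_values`,
#'   `n_values_flagged`, `n_records_flagged`, `flagged_pct` (1 dp),
#'   `n_retained`, and a `host_decisions` tibble logging every distinct
#'   host value with its verdict and record count.
#' @export
scope_records <- function(records, table = load_body_site_table(),
                          lexicon = load_host_lexicon(), threshold = 1000,
                          null_tokens = default_null_tokens()) {
  cls <- classify_body_site(records$taxonomy_id, table)
  records$body_site <- cls$body_site
  records$origin <- cls$origin

  is_generic <- !is.na(cls$origin) & cls$origin == "generic"
  generic_counts <- table(records$taxonomy_id[is_generic])
  admitted <- select_generic_categories(generic_counts, threshold)
  evaluated <- is_generic & records$taxonomy_id %in% admitted

  host <- rep(NA_character_, nrow(records))
  host[evaluated] <- derive_putative_host(records$attributes[evaluated],
                                          null_tokens)
  flagged <- rep(FALSE, nrow(records))
  distinct_vals <- unique(host[evaluated & !is.na(host)])
  verdicts <- flag_human_host(distinct_vals, lexicon)
  flagged[evaluated & !is.na(host)] <-
    verdicts[match(host[evaluated & !is.na(host)], distinct_vals)]

  keep <- (!is.na(cls$origin) & cls$origin == "human-labeled") | flagged
  n_eval <- sum(evaluated)
  n_flagged <- sum(flagged)
  host_decisions <- tibble::tibble(
    value = distinct_vals,
    flagged = verdicts,
    n_records = as.integer(table(factor(host[evaluated], levels = distinct_vals)))
  )
  report <- list(
    n_input = nrow(records),
    n_human_labeled = sum(!is.na(cls$origin) & cls$origin == "human-labeled"),
    n_generic_total = sum(is_generic),
    n_generic_evaluated = n_eval,
    admitted_generic_taxids = admitted,
    distinct_host_values = length(distinct_vals),
    n_values_flagged = sum(verdicts),
    n_records_flagged = n_flagged,
    flagged_pct = flagging_rate(n_flagged, n_eval),
    n_retained = sum(keep),
    host_decisions = host_decisions
  )
  list(records = records[keep, ], report = report)
}
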
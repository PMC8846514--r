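# Brute-force scoping oracle: a literal loop over the rules, independent of
# scope_records() internals.
oracle_scope <- function(records, table, lexicon, threshold,
                         null_tokens = default_null_tokens()) {
  # realized generic-category counts
  counts <- integer()
  for (i in seq_len(nrow(records))) {
    tid <- records$taxonomy_id[i]
    if (tid %in% table$generic_taxid) {
      key <- as.character(tid)
      counts[key] <- (if (key %in% names(counts)) counts[key] else 0L) + 1L
    }
  }
  admitted <- as.integer(names(counts)[counts >= threshold])
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    tid <- records$taxonomy_id[i]
    if (tid %in% table$human_taxid) {
      keep[i] <- TRUE
    } else if (tid %in% admitted) {
      attrs <- records$attributes[[i]]
      host <- NA_character_
      ht <- attrs[match("host_taxid", names(attrs))]
      if (length(ht) == 1 && !is.na(ht) &&
          !(tolower(trimws(ht)) %in% null_tokens)) {
        host <- unname(ht)
      } else {
        h <- attrs[match("host", names(attrs))]
        if (length(h) == 1 && !is.na(h) &&
            !(tolower(trimws(h)) %in% null_tokens)) host <- unname(h)
      }
      if (!is.na(host)) {
        if (grepl("^\\s*\\d+\\s*$", host)) {
          keep[i] <- as.integer(host) %in% lexicon$human_taxids
        } else {
          low <- tolower(host)
          veto <- any(vapply(lexicon$negative_overrides,
                             function(t) grepl(t, low, fixed = TRUE),
                             logical(1)))
          pos <- any(vapply(lexicon$positive_tokens,
                            function(t) grepl(t, low, fixed = TRUE),
                            logical(1)))
          keep[i] <- pos && !veto
        }
      }
    }
  }
  records$accession[keep]
}

# Brute-force per-country tabulation oracle.
oracle_tabulate_country <- function(records) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    unit <- if (records$geo_status[i] == "resolved") {
      records$country_name[i]
    } else "Unknown"
    out[[unit]] <- (out[[unit]] %||% 0L) + 1L
  }
  unlist(out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
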
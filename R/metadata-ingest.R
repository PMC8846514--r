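#' Attach sequencing runs to sample records
#'
#' Joins a RunInfo-style table onto records by BioSample accession. Rows
#' referencing an accession not present in `records` are dropped with a
#' warning; duplicate `(Run, BioSample)` rows are deduplicated by run
#' accession. Records referenced by zero rows get an empty run list.
#'
#' @param records records tibble.
#' @param runinfo tibble with columns `Run`, `BioSample`, `LibraryStrategy`.
#' @return `records` with a `runs` list-column of tibbles
#'   (`run`, `library_strategy`).
#' @export
link_runs <- function(records, runinfo) {
  known <- runinfo$BioSample %in% records$accession
  if (any(!known)) {
    orphans <- unique(runinfo$BioSample[!known])
    warning(sprintf("%d RunInfo row(s) reference unknown accession(s): %s",
                    sum(!known),
                    paste(utils::head(orphans, 5), collapse = ", ")),
            call. = FALSE)
    runinfo <- runinfo[known, ]
  }
  runinfo <- dplyr::distinct(runinfo, .data$Run, .data$BioSample,
                             .keep_all = TRUE)
  split_runs <- split(
    tibble::tibble(run = runinfo$Run,
                   library_strategy = runinfo$LibraryStrategy),
    factor(runinfo$BioSample, levels = records$accession))
  records$runs <- unname(split_runs)
  records
}

#' Keep only records with at least one sequencing run
#'
#' A BioSample without linked runs has no public sequencing data behind it
#' and is removed from the audit.
#'
#' @param records records tibble after [link_runs()].
#' @return Filtered records; the number removed is attached as
#'   `attr(, "n_removed")` and reported via a message.
#' @export
filter_sequenced <- function(records) {
  if (is.null(records$runs)) {
    stop_geosample("records carry no 'runs' column; apply link_runs() first",
                   "geosample_pipeline_error")
  }
  has_run <- vapply(records$runs, nrow, integer(1)) > 0
  removed <- sum(!has_run)
  if (removed > 0) {
    message(sprintf("filter_sequenced: removed %d record(s) without runs (%.1f%%)",
                    removed, 100 * removed / nrow(records)))
  }
  out <- records[has_run, ]
  attr(out, "n_removed") <- removed
  out
}

#' Keep only records released strictly before a cutoff date
#'
#' Records with a missing (or unparseable, hence `NA`) release date are
#' removed and counted separately.
#'
#' @param records records tibble.
#' @param cutoff exclusive upper bound on `release_date`.
#' @return Filtered records with attributes `n_removed_undated` and
#'   `n_removed_late`.
#' @export
filter_release_date <- function(records, cutoff = as.Date("2021-01-01")) {
  undated <- is.na(records$release_date)
  late <- !undated & records$release_date >= cutoff
  if (any(undated)) {
    message(sprintf("filter_release_date: removed %d record(s) with missing dates",
                    sum(undated)))
  }
  if (any(late)) {
    message(sprintf("filter_release_date: removed %d record(s) dated %s or later",
                    sum(late), format(cutoff)))
  }
  out <- records[!undated & !late, ]
  attr(out, "n_removed_undated") <- sum(undated)
  attr(out, "n_removed_late") <- sum(late)
  out
}

#' Count how many samples carry each metadata attribute
#'
#' By default a value equal to a null token ("missing", "not collected",
#' ...) does not count as present, matching the treatment of null geography
#' elsewhere in the pipeline; set `count_null_as_present = TRUE` to count
#' raw occurrences instead.
#'
#' @param records records tibble.
#' @param count_null_as_present logical policy flag.
#' @param null_tokens null vocabulary.
#' @return Tibble (`attribute`, `samples`) sorted by decreasing count;
#'   attributes carried by zero records do not appear.
#' @export
attribute_usage <- function(records, count_null_as_present = FALSE,
                            null_tokens = default_null_tokens()) {
  if (nrow(records) == 0) {
    return(tibble::tibble(attribute = character(), samples = integer()))
  }
  nm <- unlist(lapply(records$attributes, names), use.names = FALSE)
  val <- unlist(records$attributes, use.names = FALSE)
  if (!count_null_as_present) {
    keep <- !is_null_token(val, null_tokens)
    nm <- nm[keep]
  }
  counts <- sort(table(nm), decreasing = TRUE)
  tibble::tibble(attribute = names(counts),
                 samples = as.integer(counts))
}
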
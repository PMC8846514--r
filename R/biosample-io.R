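xml_escape_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

#' Write records as a BioSample XML document
#'
#' Emits the `BioSampleSet/BioSample/Attributes/Attribute` dialect used by
#' NCBI BioSample exports: accession and publication date as `BioSample`
#' attributes, the taxonomy ID on `Description/Organism`, and one
#' `Attribute` element (with `attribute_name`) per metadata key/value pair.
#' [parse_biosample()] round-trips this format.
#'
#' @param records tibble as produced by [generate_cohort()] or
#'   [parse_biosample()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_biosample_xml <- function(records, path) {
  if (nrow(records) == 0) {
    stop_geosample("refusing to write an empty BioSampleSet",
                   "geosample_io_error")
  }
  attr_block <- vapply(records$attributes, function(attrs) {
    if (length(attrs) == 0) return("    <Attributes/>")
    lines <- sprintf('      <Attribute attribute_name="%s">%s</Attribute>',
                     xml_escape_text(names(attrs)), xml_escape_text(attrs))
    paste0("    <Attributes>\n", paste(lines, collapse = "\n"),
           "\n    </Attributes>")
  }, character(1))
  date_attr <- ifelse(is.na(records$release_date), "",
                      sprintf(' publication_date="%s"',
                              format(records$release_date)))
  samples <- sprintf(
    paste0('  <BioSample accession="%s"%s>\n',
           '    <Description>\n      <Organism taxonomy_id="%d"/>\n',
           '    </Description>\n%s\n  </BioSample>'),
    xml_escape_text(records$accession), date_attr,
    records$taxonomy_id, attr_block)
  doc <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n<BioSampleSet>\n',
                paste(samples, collapse = "\n"), "\n</BioSampleSet>\n")
  writeLines(doc, path, useBytes = TRUE)
  invisible(path)
}

#' Write a run-linkage table as RunInfo-style CSV
#'
#' @param runs tibble with columns `Run`, `BioSample`, `LibraryStrategy`,
#'   `ReleaseDate`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_runinfo_csv <- function(runs, path) {
  readr::write_csv(runs, path)
  invisible(path)
}

#' Parse BioSample XML (or the equivalent JSON dump) into sample records
#'
#' One record per `BioSample` element. Attribute names are lower-cased,
#' trimmed, harmonized through the attribute alias table, and deduplicated
#' first-occurrence-wins (a warning reports conflicting duplicates).
#' Records lacking a taxonomy ID are emitted with the sentinel `0` and a
#' warning; taxonomy scoping drops them later. Duplicate accessions are an
#' error.
#'
#' @param path XML file path (or a `.json` file holding an array of objects
#'   with `accession`, `taxonomy_id`, `release_date`, `attributes`).
#' @param aliases attribute-name alias map ([load_attribute_aliases()]).
#' @return Records tibble (`accession`, `taxonomy_id`, `release_date`,
#'   `attributes` list-column).
#' @export
parse_biosample <- function(path, aliases = load_attribute_aliases()) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    return(parse_biosample_json(path, aliases))
  }
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      stop_geosample(paste0("malformed BioSample XML in '", path, "': ",
                            conditionMessage(e)),
                     "geosample_parse_error")
    })
  nodes <- xml2::xml_find_all(doc, "/BioSampleSet/BioSample")
  if (length(nodes) == 0) {
    return(tibble::tibble(accession = character(),
                          taxonomy_id = integer(),
                          release_date = as.Date(character()),
                          attributes = list()))
  }
  accession <- xml2::xml_attr(nodes, "accession")
  if (anyNA(accession) || any(accession == "")) {
    stop_geosample("BioSample element without an accession",
                   "geosample_parse_error")
  }
  dup <- unique(accession[duplicated(accession)])
  if (length(dup) > 0) {
    stop_geosample(paste0("duplicate accessions in input: ",
                          paste(dup, collapse = ", ")),
                   "geosample_parse_error")
  }
  release_raw <- xml2::xml_attr(nodes, "publication_date")
  release_date <- as.Date(release_raw, format = "%Y-%m-%d")
  taxid_raw <- xml2::xml_attr(
    xml2::xml_find_first(nodes, "./Description/Organism"), "taxonomy_id")
  taxonomy_id <- suppressWarnings(as.integer(taxid_raw))
  if (anyNA(taxonomy_id)) {
    missing_tax <- accession[is.na(taxonomy_id)]
    warning(sprintf("%d record(s) without a taxonomy ID (sentinel 0): %s",
                    length(missing_tax),
                    paste(utils::head(missing_tax, 5), collapse = ", ")),
            call. = FALSE)
    taxonomy_id[is.na(taxonomy_id)] <- 0L
  }
  attributes <- lapply(nodes, function(node) {
    attr_nodes <- xml2::xml_find_all(node, "./Attributes/Attribute")
    vals <- xml2::xml_text(attr_nodes)
    names(vals) <- xml2::xml_attr(attr_nodes, "attribute_name")
    normalize_attributes(vals, aliases,
                         xml2::xml_attr(node, "accession"))
  })
  tibble::tibble(accession = accession, taxonomy_id = taxonomy_id,
                 release_date = release_date, attributes = attributes)
}

parse_biosample_json <- function(path, aliases) {
  raw <- jsonlite::read_json(path)
  recs <- lapply(raw, function(r) {
    attrs <- unlist(r$attributes %||% list())
    if (is.null(attrs)) attrs <- character()
    list(accession = r$accession,
         taxonomy_id = as.integer(r$taxonomy_id %||% 0L),
         release_date = as.Date(r$release_date %||% NA_character_),
         attributes = normalize_attributes(attrs, aliases, r$accession))
  })
  accession <- vapply(recs, `[[`, character(1), "accession")
  dup <- unique(accession[duplicated(accession)])
  if (length(dup) > 0) {
    stop_geosample(paste0("duplicate accessions in input: ",
                          paste(dup, collapse = ", ")),
                   "geosample_parse_error")
  }
  tibble::tibble(
    accession = accession,
    taxonomy_id = vapply(recs, `[[`, integer(1), "taxonomy_id"),
    release_date = as.Date(vapply(recs, function(r)
      as.character(r$release_date), character(1))),
    attributes = lapply(recs, `[[`, "attributes")
  )
}

# lower-case, trim, alias-harmonize, first-occurrence-wins
normalize_attributes <- function(vals, aliases, accession) {
  if (length(vals) == 0) return(stats::setNames(character(), character()))
  nm <- tolower(trimws(names(vals)))
  hit <- aliases[fold_key(nm)]
  nm[!is.na(hit)] <- hit[!is.na(hit)]
  names(vals) <- nm
  dup <- duplicated(nm)
  if (any(dup)) {
    first_val <- vals[match(nm[dup], nm)]
    conflicting <- nm[dup][vals[dup] != first_val]
    if (length(conflicting) > 0) {
      warning(sprintf(
        "record %s: attribute(s) %s listed more than once with different values; keeping the first",
        accession, paste(unique(conflicting), collapse = ", ")),
        call. = FALSE)
    }
    vals <- vals[!dup]
  }
  vals
}

#' Read a RunInfo-style CSV
#'
#' @param path CSV with columns `Run`, `BioSample`, `LibraryStrategy`, and
#'   optionally `ReleaseDate`.
#' @return Tibble with those columns.
#' @export
read_runinfo <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    Run = readr::col_character(),
    BioSample = readr::col_character(),
    LibraryStrategy = readr::col_character(),
    .default = readr::col_character()
  ))
}
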
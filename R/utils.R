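#' Null tokens treated as missing metadata values
#'
#' INSDC-style submissions use a small vocabulary of placeholder strings in
#' place of a true missing value. Values matching one of these tokens
#' (case-insensitively, after trimming) are treated as absent geography and,
#' by default, as absent values in attribute-usage statistics.
#'
#' @return Character vector of null tokens. The empty string is included;
#'   callers distinguish empty/absent from an explicit null token.
#' @export
default_null_tokens <- function() {
  c("missing", "not collected", "not applicable", "restricted access",
    "unknown", "")
}

#' @keywords internal
is_null_token <- function(x, null_tokens = default_null_tokens()) {
  !is.na(x) & tolower(trimws(x)) %in% tolower(null_tokens)
}

#' Round half away from zero
#'
#' Presentation-layer rounding used for all printed percentages and
#' proportions, so that e.g. 0.25 rounds to 0.3 at one decimal place.
#' Internal arithmetic is always done in full precision.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Case/whitespace/diacritic-folded key for gazetteer lookups.
fold_key <- function(x) {
  x <- trimws(x)
  folded <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  folded[is.na(folded)] <- x[is.na(folded)]
  tolower(folded)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Safe lookup in a named character vector: NA when the name is absent.
attr_get <- function(attrs, name) {
  i <- match(name, names(attrs))
  if (is.na(i)) NA_character_ else unname(attrs[[i]])
}

stop_geosample <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "geosample_error"), ...)
}
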
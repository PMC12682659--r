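# Shared internal helpers: name normalization and YYYYMMDD date handling.

#' Normalize a drug name
#'
#' Uppercases, trims surrounding whitespace, and collapses internal runs of
#' whitespace. No ingredient mapping or salt stripping is attempted; brand
#' and generic spellings remain distinct strings.
#'
#' @param x Character vector of drug names.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_drug_name("  valproic   acid ")
normalize_drug_name <- function(x) {
  gsub("[[:space:]]+", " ", toupper(trimws(x)))
}

# case-folding used for preferred-term matching
fold_pt <- function(x) tolower(trimws(x))

#' Classify the precision of a YYYYMMDD-encoded date
#'
#' FAERS stores dates as integers: `YYYYMMDD` (day precision), `YYYYMM`
#' (month), or `YYYY` (year). Partial dates are retained by the readers but
#' excluded from day-resolution arithmetic such as time-to-onset.
#'
#' @param x Numeric vector of encoded dates (`NA` allowed).
#' @return Character vector with values `"day"`, `"month"`, `"year"`,
#'   `"invalid"` or `"missing"`.
#' @export
#' @examples
#' date_precision(c(20200131, 202001, 2020, 20200230, NA))
date_precision <- function(x) {
  out <- rep("invalid", length(x))
  miss <- is.na(x)
  out[miss] <- "missing"
  whole <- !miss & x == floor(x)
  yr <- whole & x >= 1000 & x <= 9999
  out[yr] <- "year"
  mo <- whole & x >= 100001 & x <= 999912 & (x %% 100) >= 1 & (x %% 100) <= 12
  out[mo] <- "month"
  dy <- whole & x >= 10000101 & x <= 99991231
  if (any(dy)) {
    valid <- dy
    valid[dy] <- !is.na(int_to_date(x[dy]))
    out[valid] <- "day"
    out[dy & !valid] <- "invalid"
  }
  out
}

#' Convert a YYYYMMDD integer to a Date
#'
#' Values that do not encode a valid calendar day yield `NA`.
#'
#' @param x Numeric vector of `YYYYMMDD` integers.
#' @return A `Date` vector.
#' @export
int_to_date <- function(x) {
  s <- rep(NA_character_, length(x))
  ok <- !is.na(x) & x >= 10000101 & x <= 99991231 & x == floor(x)
  if (any(ok)) s[ok] <- sprintf("%08d", x[ok])
  as.Date(s, format = "%Y%m%d")
}

#' Convert a Date to a YYYYMMDD integer
#'
#' @param d A `Date` vector.
#' @return Integer vector of `YYYYMMDD` values.
#' @export
date_to_int <- function(d) {
  lt <- as.POSIXlt(d)
  as.integer((lt$year + 1900L) * 10000L + (lt$mon + 1L) * 100L + lt$mday)
}
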
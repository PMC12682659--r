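# Ingestion of FAERS-style quarterly ASCII extracts.
#
# The quarterly files are "$"-delimited with a single header line and no
# quoting dialect, so fields are split literally on "$". A data line whose
# field count disagrees with the header is quarantined (recorded in the parse
# report) rather than silently dropped: embedded "$" in free text is treated
# as a malformed line.

# key columns: absence is a schema error
faers_required_columns <- list(
  DEMO = c("primaryid", "caseid", "fda_dt"),
  DRUG = c("primaryid", "drug_seq", "drugname", "role_cod"),
  REAC = c("primaryid", "pt"),
  THER = c("primaryid", "dsg_drug_seq", "start_dt"),
  OUTC = c("primaryid", "outc_cod")
)

# columns filled with NA when a quarter omits them (layouts drift over the
# years); anything beyond the union passes through untouched
faers_autofill_columns <- list(
  DEMO = c("event_dt", "age", "age_cod", "sex", "wt", "wt_cod",
           "reporter_country", "occp_cod")
)

faers_numeric_columns <- c(
  "primaryid", "caseid", "fda_dt", "event_dt", "drug_seq", "dsg_drug_seq",
  "start_dt", "end_dt", "age", "wt"
)

faers_role_codes <- c("PS", "SS", "C", "I")

# split on "$" keeping trailing empty fields (strsplit drops them, hence the
# sentinel appended to every line)
split_dollar <- function(lines) {
  parts <- strsplit(paste0(lines, "\x01"), "$", fixed = TRUE)
  lapply(parts, function(p) {
    p[length(p)] <- sub("\x01$", "", p[length(p)])
    p
  })
}

#' Read one FAERS quarterly ASCII table
#'
#' Reads a `$`-delimited FAERS extract file (`DEMO`, `DRUG`, `REAC`, `THER`
#' or `OUTC`). The header may contain any superset of the key columns for
#' the table kind (real quarters add columns over the years); a missing key
#' column (e.g. `primaryid`) is a schema error naming the column, while
#' absent DEMO demographic columns are filled with `NA`. Data lines whose
#' field count does not match the header are quarantined and reported via
#' the parse report attached as the `"parse_report"` attribute (see
#' [parse_report()]).
#'
#' Empty fields become `NA`. Key and date columns (`primaryid`, `caseid`,
#' `fda_dt`, ...) are converted to numeric; partial dates such as `YYYYMM`
#' survive conversion and are flagged downstream by [date_precision()].
#'
#' @param path Path to the ASCII file.
#' @param table Table kind: `"DEMO"`, `"DRUG"`, `"REAC"`, `"THER"` or
#'   `"OUTC"`.
#' @return A tibble with one row per well-formed data line, columns named
#'   after the (lower-cased) header.
#' @export
read_faers_table <- function(path, table = c("DEMO", "DRUG", "REAC", "THER", "OUTC")) {
  table <- match.arg(toupper(table[1]), names(faers_required_columns))
  if (!file.exists(path)) {
    stop("FAERS file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    stop("FAERS file is empty (no header line): ", path, call. = FALSE)
  }
  header <- tolower(split_dollar(lines[1])[[1]])
  required <- faers_required_columns[[table]]
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s header is missing required column(s): %s",
                 table, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  body <- lines[-1]
  body <- body[!(seq_along(body) == length(body) & body == "")]  # trailing blank
  fields <- split_dollar(body)
  len <- lengths(fields)
  ok <- len == length(header)
  quarantined <- tibble(
    line = which(!ok) + 1L,  # 1-based file line number (header is line 1)
    n_fields = len[!ok],
    content = body[!ok]
  )
  if (any(ok)) {
    m <- matrix(unlist(fields[ok], use.names = FALSE),
                ncol = length(header), byrow = TRUE)
    out <- as_tibble(as.data.frame(m, stringsAsFactors = FALSE),
                     .name_repair = "minimal")
    names(out) <- header
  } else {
    out <- as_tibble(setNames(rep(list(character()), length(header)), header))
  }
  out <- mutate(out, across(everything(), ~ na_if(.x, "")))
  for (col in setdiff(faers_autofill_columns[[table]] %||% character(), names(out))) {
    out[[col]] <- NA_character_
  }
  num_cols <- intersect(faers_numeric_columns, names(out))
  out <- mutate(out, across(all_of(num_cols),
                            ~ suppressWarnings(as.numeric(.x))))
  attr(out, "parse_report") <- list(
    table = table,
    n_rows = sum(ok),
    n_quarantined = sum(!ok),
    quarantined = quarantined
  )
  out
}

#' Retrieve the parse report of a table read by [read_faers_table()]
#'
#' @param x A tibble returned by [read_faers_table()].
#' @return A list with elements `table`, `n_rows`, `n_quarantined` and the
#'   `quarantined` tibble of malformed lines.
#' @export
parse_report <- function(x) {
  attr(x, "parse_report", exact = TRUE)
}

#' Write a FAERS-style ASCII table
#'
#' Inverse of [read_faers_table()]: writes a `$`-delimited file with one
#' header line. `NA` becomes the empty field; numbers are printed without
#' scientific notation so that read-back is value-identical. A field value
#' containing `$` cannot be represented in this dialect and is an error.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(x, path) {
  cols <- lapply(x, function(v) {
    if (is.numeric(v)) {
      s <- format(v, scientific = FALSE, trim = TRUE)
    } else {
      s <- as.character(v)
    }
    s[is.na(v)] <- ""
    s
  })
  if (any(vapply(cols, function(s) any(grepl("$", s, fixed = TRUE)), logical(1)))) {
    stop("field values may not contain '$' in the FAERS ASCII dialect",
         call. = FALSE)
  }
  lines <- c(paste(names(x), collapse = "$"),
             if (nrow(x) > 0L) do.call(paste, c(cols, sep = "$")))
  writeLines(lines, path)
  invisible(path)
}

#' Read the five tables of a FAERS-style quarter from a directory
#'
#' Expects the file layout written by [generate_quarter()]: `DEMO.txt`,
#' `DRUG.txt`, `REAC.txt`, `THER.txt`, `OUTC.txt`.
#'
#' @param dir Directory containing the five files.
#' @return A named list of tibbles (`demo`, `drug`, `reac`, `ther`, `outc`).
#' @export
read_faers_quarter <- function(dir) {
  kinds <- c("DEMO", "DRUG", "REAC", "THER", "OUTC")
  out <- lapply(kinds, function(k) {
    read_faers_table(file.path(dir, paste0(k, ".txt")), k)
  })
  setNames(out, tolower(kinds))
}

#' Low-level constructor for an assembled report set
#'
#' A `faers_reports` object is a relational container with one row per
#' report in `demo` and child tables keyed by `primaryid`. Drug names are
#' normalized with [normalize_drug_name()] and role codes validated against
#' `PS`/`SS`/`C`/`I` (unknown codes are rejected).
#'
#' @param demo Tibble with one row per report (must contain `primaryid`,
#'   `caseid`, `fda_dt`; demographic columns optional).
#' @param drugs Tibble of drug entries (`primaryid`, `drug_seq`, `drugname`,
#'   `role_cod`, optionally `start_dt`).
#' @param reactions Tibble of reaction preferred terms (`primaryid`, `pt`).
#' @param outcomes Tibble of outcome codes (`primaryid`, `outc_cod`).
#' @return An object of class `faers_reports`.
#' @export
faers_reports <- function(demo,
                          drugs = tibble(primaryid = numeric(), drug_seq = numeric(),
                                         drugname = character(), role_cod = character(),
                                         start_dt = numeric()),
                          reactions = tibble(primaryid = numeric(), pt = character()),
                          outcomes = tibble(primaryid = numeric(), outc_cod = character())) {
  demo <- as_tibble(demo)
  drugs <- as_tibble(drugs)
  reactions <- as_tibble(reactions)
  outcomes <- as_tibble(outcomes)
  for (col in c("primaryid", "caseid", "fda_dt")) {
    if (!col %in% names(demo)) {
      stop("demo is missing required column: ", col, call. = FALSE)
    }
  }
  for (col in faers_autofill_columns$DEMO) {
    if (!col %in% names(demo)) demo[[col]] <- NA
  }
  if (nrow(drugs) > 0L) {
    drugs$drugname <- normalize_drug_name(drugs$drugname)
    bad <- setdiff(unique(drugs$role_cod), faers_role_codes)
    if (length(bad) > 0L) {
      stop("unknown drug role code(s): ", paste(bad, collapse = ", "),
           " (expected PS, SS, C or I)", call. = FALSE)
    }
  }
  if (!"start_dt" %in% names(drugs)) drugs$start_dt <- NA_real_
  structure(
    list(demo = demo, drugs = drugs, reactions = reactions, outcomes = outcomes),
    class = "faers_reports"
  )
}

#' Number of reports in a `faers_reports` object
#'
#' @param x A `faers_reports` object.
#' @return Integer count of reports (rows of the DEMO table).
#' @export
n_reports <- function(x) {
  stopifnot(inherits(x, "faers_reports"))
  nrow(x$demo)
}

#' @export
print.faers_reports <- function(x, ...) {
  cat("<faers_reports>\n")
  cat(sprintf("  reports:   %d\n", nrow(x$demo)))
  cat(sprintf("  drugs:     %d entries (%d distinct names)\n",
              nrow(x$drugs), n_distinct(x$drugs$drugname)))
  cat(sprintf("  reactions: %d entries (%d distinct PTs)\n",
              nrow(x$reactions), n_distinct(x$reactions$pt)))
  cat(sprintf("  outcomes:  %d entries\n", nrow(x$outcomes)))
  orphans <- attr(x, "orphans")
  if (!is.null(orphans)) {
    cat("  orphan child rows dropped:",
        paste(sprintf("%s=%d", names(orphans), orphans), collapse = ", "), "\n")
  }
  invisible(x)
}

# earliest start date preferring day precision; falls back to the earliest
# partial value so the exclusion reason downstream is "partial", not "missing"
pick_start <- function(start_dt) {
  prec <- date_precision(start_dt)
  full <- start_dt[prec == "day"]
  if (length(full) > 0L) return(min(full))
  present <- start_dt[!is.na(start_dt)]
  if (length(present) > 0L) return(min(present))
  NA_real_
}

#' Assemble parsed FAERS tables into per-report records
#'
#' Joins the five quarterly tables on `primaryid` into a [faers_reports()]
#' container: one report per DEMO row with attached drug entries (therapy
#' start dates matched by `(primaryid, dsg_drug_seq)`), reaction preferred
#' terms and outcome codes. Child rows whose `primaryid` matches no DEMO row
#' are orphans: they are counted in the `"orphans"` attribute and excluded,
#' never silently dropped.
#'
#' Deduplication ([deduplicate()]) is a key-level preprocessing step and is
#' expected to run before assembly; duplicate `primaryid` values in `demo`
#' are therefore an error unless `tolerate_duplicates = TRUE`.
#'
#' @param demo,drug,reac,ther,outc Tibbles as returned by
#'   [read_faers_table()] (`ther` and `outc` may be `NULL`).
#' @param tolerate_duplicates Keep duplicated `primaryid` rows in `demo`
#'   instead of failing.
#' @return A [faers_reports()] object with an `"orphans"` attribute giving
#'   per-table orphan row counts.
#' @export
assemble_reports <- function(demo, drug, reac, ther = NULL, outc = NULL,
                             tolerate_duplicates = FALSE) {
  demo <- as_tibble(demo)
  if (anyDuplicated(demo$primaryid) && !tolerate_duplicates) {
    dups <- unique(demo$primaryid[duplicated(demo$primaryid)])
    stop("duplicate primaryid in DEMO input (run deduplication first or set ",
         "tolerate_duplicates = TRUE); e.g. primaryid ", dups[1], call. = FALSE)
  }
  ids <- demo$primaryid
  if (is.null(ther)) ther <- tibble(primaryid = numeric(), dsg_drug_seq = numeric(),
                                    start_dt = numeric())
  if (is.null(outc)) outc <- tibble(primaryid = numeric(), outc_cod = character())
  orphans <- c(
    drug = sum(!drug$primaryid %in% ids),
    reac = sum(!reac$primaryid %in% ids),
    ther = sum(!ther$primaryid %in% ids),
    outc = sum(!outc$primaryid %in% ids)
  )
  drug <- filter(drug, .data$primaryid %in% ids)
  reac <- filter(reac, .data$primaryid %in% ids)
  ther <- filter(ther, .data$primaryid %in% ids)
  outc <- filter(outc, .data$primaryid %in% ids)

  ther_start <- ther |>
    group_by(.data$primaryid, .data$dsg_drug_seq) |>
    summarise(start_dt = pick_start(.data$start_dt), .groups = "drop")
  drug <- drug |>
    select(-any_of("start_dt")) |>
    left_join(ther_start,
              by = c("primaryid", "drug_seq" = "dsg_drug_seq"))

  out <- faers_reports(
    demo = demo,
    drugs = select(drug, any_of(c("primaryid", "drug_seq", "drugname",
                                  "role_cod", "start_dt"))),
    reactions = select(reac, "primaryid", "pt"),
    outcomes = select(outc, "primaryid", "outc_cod")
  )
  attr(out, "orphans") <- orphans
  out
}
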
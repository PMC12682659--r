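# Case deduplication.
#
# FAERS publishes one row per report *version*; a case (CASEID) accumulates
# versions over time. Following FDA practice, one version is retained per
# case: the one with the latest FDA receipt date (FDA_DT), ties broken by
# the highest PRIMARYID. Both stated forms of the tie rule reduce to a
# lexicographic maximum on (fda_dt, primaryid).

#' Deduplicate report keys
#'
#' Applies the one-version-per-case rule to a set of report keys: within
#' each `caseid` group the key with the latest `fda_dt` is retained, ties on
#' `fda_dt` broken by the highest `primaryid`. A key with missing `fda_dt`
#' sorts as earliest (it is never retained unless it is the only version)
#' and triggers a warning.
#'
#' @param keys Data frame with columns `caseid`, `primaryid`, `fda_dt`.
#'   `caseid` and `primaryid` must be non-missing and `primaryid` unique.
#' @return A tibble of class `dedup_decisions`, sorted by `caseid` then
#'   `primaryid`, with columns `caseid`, `primaryid`, `fda_dt`, `retained`
#'   (logical) and `reason` (`only_version`, `latest_fda_dt`,
#'   `highest_primaryid` for retained rows; `superseded` otherwise).
#' @export
#' @examples
#' keys <- tibble::tibble(
#'   caseid = 4070800,
#'   fda_dt = c(20040113, 20040113, 20040130, 20040308),
#'   primaryid = c(4271953, 4271960, 4283861, 4314767)
#' )
#' deduplicate(keys)
deduplicate <- function(keys) {
  keys <- as_tibble(keys)
  for (col in c("caseid", "primaryid", "fda_dt")) {
    if (!col %in% names(keys)) {
      stop("keys is missing required column: ", col, call. = FALSE)
    }
  }
  if (anyNA(keys$caseid) || anyNA(keys$primaryid)) {
    stop("caseid and primaryid must be non-missing for deduplication",
         call. = FALSE)
  }
  if (anyDuplicated(keys$primaryid)) {
    stop("primaryid values must be unique report-version identifiers",
         call. = FALSE)
  }
  if (anyNA(keys$fda_dt)) {
    warning("missing fda_dt treated as earliest within its case group",
            call. = FALSE)
  }
  keys |>
    select("caseid", "primaryid", "fda_dt") |>
    mutate(.fda = coalesce(as.numeric(.data$fda_dt), -Inf)) |>
    group_by(.data$caseid) |>
    mutate(
      .n = n(),
      .maxfda = max(.data$.fda),
      .ntie = sum(.data$.fda == .data$.maxfda),
      retained = .data$.fda == .data$.maxfda &
        .data$primaryid == max(.data$primaryid[.data$.fda == .data$.maxfda]),
      reason = case_when(
        !.data$retained ~ "superseded",
        .data$.n == 1L ~ "only_version",
        .data$.ntie == 1L ~ "latest_fda_dt",
        TRUE ~ "highest_primaryid"
      )
    ) |>
    ungroup() |>
    arrange(.data$caseid, .data$primaryid) |>
    select("caseid", "primaryid", "fda_dt", "retained", "reason") |>
    structure(class = c("dedup_decisions", "tbl_df", "tbl", "data.frame"))
}

#' Deduplicate an assembled report set
#'
#' Runs [deduplicate()] on the DEMO keys of a [faers_reports()] object and
#' filters every table down to the retained report versions. The full
#' decision table is attached as the `"dedup_decisions"` attribute for
#' auditing (see [write_dedup_audit()]).
#'
#' @param reports A [faers_reports()] object.
#' @return A deduplicated [faers_reports()] object.
#' @export
dedup_reports <- function(reports) {
  stopifnot(inherits(reports, "faers_reports"))
  decisions <- deduplicate(reports$demo)
  keep <- decisions$primaryid[decisions$retained]
  out <- faers_reports(
    demo = filter(reports$demo, .data$primaryid %in% keep),
    drugs = filter(reports$drugs, .data$primaryid %in% keep),
    reactions = filter(reports$reactions, .data$primaryid %in% keep),
    outcomes = filter(reports$outcomes, .data$primaryid %in% keep)
  )
  attr(out, "orphans") <- attr(reports, "orphans")
  attr(out, "dedup_decisions") <- decisions
  out
}

#' Write a deduplication audit log
#'
#' Tab-delimited export of every key with a Yes/No deletion column, one row
#' per report version, mirroring the layout of the worked deduplication
#' example shipped in the methods vignette.
#'
#' @param decisions A `dedup_decisions` tibble from [deduplicate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dedup_audit <- function(decisions, path) {
  out <- decisions |>
    mutate(delete = ifelse(.data$retained, "No", "Yes")) |>
    select("caseid", "fda_dt", "primaryid", "delete", "reason")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
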
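# Case selection: which reports carry the target event, and which
# (drug, report) pairs count as exposure.
#
# The unit of counting is the report (primaryid), never the drug-reaction
# line, so a drug repeated within one report contributes once. Only entries
# whose role code is PS (primary suspect) count as exposure; secondary
# suspect, concomitant and interacting entries are excluded.

#' Define a target adverse event by MedDRA preferred terms
#'
#' Matching is exact after case folding (lower-casing and trimming); no
#' MedDRA hierarchy traversal or SMQ expansion is performed, so the term
#' list must enumerate every preferred-term spelling of interest.
#'
#' @param pt_terms Non-empty character vector of preferred-term strings.
#' @return An object of class `event_definition`.
#' @export
#' @examples
#' event_definition(c("Polycystic ovaries", "Polycystic ovary syndrome"))
event_definition <- function(pt_terms) {
  pt_terms <- as.character(pt_terms)
  if (length(pt_terms) == 0L || anyNA(pt_terms) || any(!nzchar(trimws(pt_terms)))) {
    stop("pt_terms must be a non-empty character vector without empty strings",
         call. = FALSE)
  }
  structure(list(pt_terms = pt_terms), class = "event_definition")
}

#' Read an event definition from a YAML config file
#'
#' The file must contain a `pt_terms` key listing preferred-term strings.
#'
#' @param path Path to a YAML file.
#' @return An [event_definition()].
#' @export
read_event_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pt_terms)) {
    stop("event config must contain a 'pt_terms' key", call. = FALSE)
  }
  event_definition(unlist(cfg$pt_terms))
}

as_pt_terms <- function(event) {
  if (inherits(event, "event_definition")) return(event$pt_terms)
  event_definition(event)$pt_terms
}

#' Select reports carrying the target event
#'
#' A report is selected iff any of its reaction preferred terms equals
#' (case-folded) any term of the event definition.
#'
#' @param reports A deduplicated [faers_reports()] object.
#' @param event An [event_definition()] or character vector of PT strings.
#' @return Sorted numeric vector of selected `primaryid`s.
#' @export
select_event_cases <- function(reports, event) {
  stopifnot(inherits(reports, "faers_reports"))
  terms <- fold_pt(as_pt_terms(event))
  rx <- reports$reactions
  sort(unique(rx$primaryid[fold_pt(rx$pt) %in% terms]))
}

#' Extract primary-suspect (drug, report) pairs
#'
#' One pair per report and *distinct* primary-suspect drug name: a report
#' listing the same PS drug twice yields one pair; a report with two
#' different PS drugs yields two. SS/C/I entries contribute nothing.
#'
#' @param reports A [faers_reports()] object.
#' @param case_ids Optional vector of `primaryid`s to restrict to (e.g. the
#'   selected event cases). `NULL` keeps all reports.
#' @return Tibble with columns `primaryid`, `drugname`.
#' @export
primary_suspect_pairs <- function(reports, case_ids = NULL) {
  stopifnot(inherits(reports, "faers_reports"))
  d <- filter(reports$drugs, .data$role_cod == "PS")
  if (!is.null(case_ids)) d <- filter(d, .data$primaryid %in% case_ids)
  d |>
    distinct(.data$primaryid, .data$drugname) |>
    arrange(.data$primaryid, .data$drugname)
}

#' Count the marginals feeding the disproportionality tables
#'
#' Report-level counts over the full deduplicated universe: `n_total` is
#' every report in the study window (the `d` cell of the 2x2 table needs
#' non-event, non-drug reports), `n_event` the reports carrying the target
#' event, and per drug the number of reports naming it as primary suspect
#' (`n_drug`, the future `a + b`) and the subset of those that also carry
#' the event (`n_drug_event`, the future `a`).
#'
#' @inheritParams select_event_cases
#' @return A tibble of class `faers_marginals` with columns `drugname`,
#'   `n_drug`, `n_drug_event`, plus attributes `n_total`, `n_event` and
#'   `pt_terms`.
#' @export
count_marginals <- function(reports, event) {
  stopifnot(inherits(reports, "faers_reports"))
  cases <- select_event_cases(reports, event)
  pairs <- primary_suspect_pairs(reports)
  per_drug <- pairs |>
    group_by(.data$drugname) |>
    summarise(
      n_drug = n(),
      n_drug_event = sum(.data$primaryid %in% cases),
      .groups = "drop"
    ) |>
    arrange(desc(.data$n_drug_event), desc(.data$n_drug), .data$drugname)
  structure(
    per_drug,
    n_total = nrow(reports$demo),
    n_event = length(cases),
    pt_terms = as_pt_terms(event),
    class = c("faers_marginals", class(per_drug))
  )
}

#' Expand marginal counts into 2x2 contingency tables
#'
#' For each drug: `a` = reports naming the drug (PS) with the target event,
#' `b` = drug without the event, `c` = event without the drug, `d` = neither.
#'
#' @param marginals A `faers_marginals` object from [count_marginals()].
#' @return Tibble with columns `drugname`, `a`, `b`, `c`, `d`.
#' @export
contingency_tables <- function(marginals) {
  stopifnot(inherits(marginals, "faers_marginals"))
  n_total <- attr(marginals, "n_total")
  n_event <- attr(marginals, "n_event")
  out <- tibble(
    drugname = marginals$drugname,
    a = marginals$n_drug_event,
    b = marginals$n_drug - marginals$n_drug_event,
    c = n_event - marginals$n_drug_event,
    d = n_total - n_event - (marginals$n_drug - marginals$n_drug_event)
  )
  if (any(out$a < 0 | out$b < 0 | out$c < 0 | out$d < 0)) {
    stop("negative contingency cell: marginal counts are inconsistent",
         call. = FALSE)
  }
  out
}
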
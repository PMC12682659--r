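# Descriptive reporting over the selected event cases: yearly counts,
# country of origin, reporter occupation, age and weight distributions,
# and outcome codes.

#' Default FAERS reporter-occupation labels
#'
#' Maps FAERS `occp_cod` values to display categories. The mapping is
#' configurable because reporter categories in published summaries do not
#' map one-to-one onto the raw codes.
#'
#' @return Named character vector (code -> label).
#' @export
faers_reporter_map <- function() {
  c(CN = "Consumer", MD = "Physician", OT = "Other health professional",
    PH = "Pharmacist", RN = "Nurse", LW = "Lawyer", HP = "Other health professional")
}

faers_outcome_labels <- c(
  DE = "Death", LT = "Life-threatening", HO = "Hospitalization",
  DS = "Disability", CA = "Congenital anomaly",
  RI = "Required intervention", OT = "Other"
)

# years per unit of each FAERS age code
age_unit_years <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 7 / 365.25,
                    DY = 1 / 365.25, HR = 1 / 8766)

weight_unit_kg <- c(KG = 1, KGS = 1, LBS = 0.453592, GMS = 0.001)

#' Convert FAERS age values to years
#'
#' Decades are multiplied by 10, months divided by 12, and so on. An
#' unknown unit code yields `NA` (binned as unknown downstream).
#'
#' @param age Numeric age values.
#' @param age_cod Unit codes (`DEC`, `YR`, `MON`, `WK`, `DY`, `HR`).
#' @return Numeric vector of ages in years.
#' @export
age_in_years <- function(age, age_cod) {
  factor_ <- unname(age_unit_years[age_cod])
  age * factor_
}

#' Convert FAERS weight values to kilograms
#'
#' @param wt Numeric weights.
#' @param wt_cod Unit codes (`KG`, `KGS`, `LBS`, `GMS`).
#' @return Numeric vector of weights in kg.
#' @export
weight_in_kg <- function(wt, wt_cod) {
  wt * unname(weight_unit_kg[wt_cod])
}

count_pct <- function(x, levels, total) {
  f <- factor(x, levels = levels)
  tab <- table(f)
  tibble(
    category = names(tab),
    n = as.integer(tab),
    pct = round(100 * as.integer(tab) / total, 2)
  )
}

#' Descriptive summary of a set of event reports
#'
#' Tabulates the selected (deduplicated, event-matched) reports by receipt
#' year, reporting country, reporter occupation, age decade, 10-kg weight
#' band, and outcome code. Ages and weights are converted to years/kg from
#' their unit codes before binning; reports with missing or unconvertible
#' values land in an explicit `Unknown` category, so every report falls in
#' exactly one age bin and one weight bin. Outcome percentages are per
#' outcome *mention* over the report total (a report can carry several
#' outcome codes, so these percentages can exceed 100 in sum).
#'
#' @param reports A [faers_reports()] object.
#' @param case_ids Optional vector of `primaryid`s to restrict to (e.g.
#'   from [select_event_cases()]); `NULL` summarises all reports.
#' @param reporter_map Named code-to-label vector, see
#'   [faers_reporter_map()].
#' @return A list of class `faers_description` with tibbles `by_year`,
#'   `by_country`, `by_reporter`, `by_age`, `by_weight`, `by_outcome`, and
#'   attributes `n_reports` and `n_unknown_age_unit`.
#' @export
describe_reports <- function(reports, case_ids = NULL,
                             reporter_map = faers_reporter_map()) {
  stopifnot(inherits(reports, "faers_reports"))
  demo <- reports$demo
  if (!is.null(case_ids)) demo <- filter(demo, .data$primaryid %in% case_ids)
  total <- nrow(demo)
  if (total == 0L) stop("no reports to describe", call. = FALSE)

  by_year <- demo |>
    mutate(year = .data$fda_dt %/% 10000) |>
    count(.data$year, name = "n") |>
    arrange(.data$year)

  by_country <- demo |>
    mutate(country = coalesce(.data$reporter_country, "Unknown")) |>
    count(.data$country, name = "n", sort = TRUE)

  rep_label <- unname(reporter_map[demo$occp_cod])
  rep_label[is.na(rep_label)] <- "Unknown"
  rep_levels <- c(unique(unname(reporter_map)), "Unknown")
  by_reporter <- count_pct(rep_label, rep_levels, total) |>
    filter(.data$n > 0 | .data$category != "Unknown") |>
    arrange(desc(.data$n))

  yrs <- age_in_years(demo$age, demo$age_cod)
  n_unknown_unit <- sum(!is.na(demo$age) & !is.na(demo$age_cod) &
                          !demo$age_cod %in% names(age_unit_years))
  age_levels <- c(paste(seq(0, 80, 10), seq(9, 89, 10), sep = "-"), "90+", "Unknown")
  age_bin <- as.character(cut(yrs, breaks = c(seq(0, 90, 10), Inf),
                              labels = head(age_levels, -1), right = FALSE))
  age_bin[is.na(age_bin)] <- "Unknown"
  by_age <- count_pct(age_bin, age_levels, total)

  kg <- weight_in_kg(demo$wt, demo$wt_cod)
  wt_levels <- c(paste(seq(0, 90, 10), seq(9, 99, 10), sep = "-"), ">100", "Unknown")
  wt_bin <- as.character(cut(kg, breaks = c(seq(0, 100, 10), Inf),
                             labels = head(wt_levels, -1), right = FALSE))
  wt_bin[is.na(wt_bin)] <- "Unknown"
  by_weight <- count_pct(wt_bin, wt_levels, total)

  outc <- reports$outcomes
  outc <- filter(outc, .data$primaryid %in% demo$primaryid)
  by_outcome <- outc |>
    count(.data$outc_cod, name = "n", sort = TRUE) |>
    mutate(
      outcome = coalesce(unname(faers_outcome_labels[.data$outc_cod]),
                         .data$outc_cod),
      pct = round(100 * .data$n / total, 2)
    ) |>
    select("outc_cod", "outcome", "n", "pct")

  structure(
    list(by_year = by_year, by_country = by_country, by_reporter = by_reporter,
         by_age = by_age, by_weight = by_weight, by_outcome = by_outcome),
    n_reports = total,
    n_unknown_age_unit = n_unknown_unit,
    class = "faers_description"
  )
}

#' @export
print.faers_description <- function(x, ...) {
  cat(sprintf("<faers_description> of %d reports\n", attr(x, "n_reports")))
  for (nm in names(x)) {
    cat("\n--", nm, "--\n")
    print(x[[nm]], n = 6)
  }
  invisible(x)
}
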
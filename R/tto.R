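# Time-to-onset: days from therapy start to adverse-event onset.
#
# Both dates must be full-precision (YYYYMMDD) calendar dates; partial,
# missing, invalid, or negative differences are excluded with a logged
# reason. Quantiles use linear interpolation between order statistics
# (position h = (n-1)p), which is what produces fractional day values such
# as quarter- and half-day medians in published onset tables.

#' Calendar-day difference between therapy start and event onset
#'
#' Vectorized over pairs of `YYYYMMDD`-encoded dates. A pair is excluded
#' (days `NA`) when either date is missing, partial (`YYYYMM`/`YYYY`),
#' invalid as a calendar date, or when the difference is negative.
#'
#' @param start_dt,event_dt Numeric vectors of encoded dates.
#' @return Tibble with columns `start_dt`, `event_dt`, `days` (integer, `NA`
#'   unless `status == "ok"`) and `status` (`ok`, `negative`, `partial`,
#'   `invalid`, `missing`).
#' @export
#' @examples
#' onset_days(20200101, 20200131)
onset_days <- function(start_dt, event_dt) {
  n <- max(length(start_dt), length(event_dt))
  start_dt <- rep_len(start_dt, n)
  event_dt <- rep_len(event_dt, n)
  p_s <- date_precision(start_dt)
  p_e <- date_precision(event_dt)
  status <- rep("ok", n)
  status[p_s %in% c("month", "year") | p_e %in% c("month", "year")] <- "partial"
  status[p_s == "invalid" | p_e == "invalid"] <- "invalid"
  status[p_s == "missing" | p_e == "missing"] <- "missing"
  days <- rep(NA_integer_, n)
  ok <- status == "ok"
  if (any(ok)) {
    d <- as.integer(int_to_date(event_dt[ok]) - int_to_date(start_dt[ok]))
    neg <- d < 0
    status[ok][neg] <- "negative"
    d[neg] <- NA_integer_
    days[ok] <- d
  }
  tibble(start_dt = start_dt, event_dt = event_dt, days = days, status = status)
}

#' Extract per-drug onset records from an assembled report set
#'
#' For every selected event case and every primary-suspect drug it names,
#' the onset is the event date minus the earliest *full-precision* therapy
#' start among that drug's entries (the conservative exposure origin).
#' Records that cannot be computed are excluded; the per-reason exclusion
#' counts are attached as the `"excluded"` attribute.
#'
#' @inheritParams select_event_cases
#' @param drugs Optional character vector restricting to these drug names
#'   (normalized before matching).
#' @return Tibble with columns `drugname`, `primaryid`, `days` (one row per
#'   valid onset record), with attribute `excluded` (tibble of `status`,
#'   `n`).
#' @export
tto_records <- function(reports, event, drugs = NULL) {
  stopifnot(inherits(reports, "faers_reports"))
  cases <- select_event_cases(reports, event)
  ps <- filter(reports$drugs, .data$role_cod == "PS", .data$primaryid %in% cases)
  if (!is.null(drugs)) {
    ps <- filter(ps, .data$drugname %in% normalize_drug_name(drugs))
  }
  best <- ps |>
    group_by(.data$primaryid, .data$drugname) |>
    summarise(start_dt = pick_start(.data$start_dt), .groups = "drop")
  joined <- left_join(best,
                      select(reports$demo, "primaryid", "event_dt"),
                      by = "primaryid")
  od <- onset_days(joined$start_dt, joined$event_dt)
  all_rec <- tibble(
    drugname = joined$drugname,
    primaryid = joined$primaryid,
    days = od$days,
    status = od$status
  )
  excluded <- all_rec |>
    filter(.data$status != "ok") |>
    count(.data$status, name = "n")
  out <- all_rec |>
    filter(.data$status == "ok") |>
    select("drugname", "primaryid", "days")
  attr(out, "excluded") <- excluded
  out
}

onset_bin_labels <- c("0-30",
                      paste(seq(31, 331, by = 30), seq(60, 360, by = 30), sep = "-"),
                      ">360")

#' Bin onset days into the fixed 30-day scheme
#'
#' Bins are `0-30`, `31-60`, ..., `331-360` and an open `>360` bin. The
#' boundary convention is inclusive on the right: day 30 falls in `0-30`,
#' day 31 in `31-60`, day 361 and later in `>360`. Day-0 onsets (start on
#' the event date) are kept in `0-30`.
#'
#' @param days Non-negative integer vector of onset days.
#' @return Tibble with columns `bin` (ordered factor over all 13 labels)
#'   and `n`; counts sum to `length(days)`.
#' @export
#' @examples
#' bin_onsets(c(0, 30, 31, 360, 361))
bin_onsets <- function(days) {
  if (length(days) > 0 && (anyNA(days) || any(days < 0))) {
    stop("onset days must be non-negative and non-missing", call. = FALSE)
  }
  f <- cut(days, breaks = c(-1, seq(30, 360, by = 30), Inf),
           labels = onset_bin_labels)
  tibble(
    bin = factor(onset_bin_labels, levels = onset_bin_labels),
    n = as.integer(table(f))
  )
}

#' Per-drug time-to-onset summary
#'
#' Median and quartiles by linear interpolation between order statistics
#' (quantile position `h = (n-1)p`, R's default type-7 convention) plus the
#' binned 30-day histogram for each drug.
#'
#' @param records Onset records from [tto_records()] (columns `drugname`,
#'   `days`).
#' @return A tibble of class `faers_tto` with columns `drugname`, `n`,
#'   `q1`, `median`, `q3` and a `bins` list-column of [bin_onsets()]
#'   histograms.
#' @export
#' @examples
#' tto_summary(tibble::tibble(drugname = "X", days = c(10, 20, 30, 40)))
tto_summary <- function(records) {
  stopifnot(all(c("drugname", "days") %in% names(records)))
  if (nrow(records) == 0L) {
    stop("no onset records to summarise", call. = FALSE)
  }
  out <- records |>
    group_by(.data$drugname) |>
    summarise(
      n = n(),
      q1 = unname(quantile(.data$days, 0.25, type = 7)),
      median = unname(quantile(.data$days, 0.5, type = 7)),
      q3 = unname(quantile(.data$days, 0.75, type = 7)),
      bins = list(bin_onsets(.data$days)),
      .groups = "drop"
    ) |>
    arrange(desc(.data$n), .data$drugname)
  structure(out, class = c("faers_tto", class(out)))
}

#' Empirical cumulative onset distribution per drug
#'
#' Step-function support points of the onset ECDF: for each drug, the
#' distinct sorted onset days with the cumulative fraction of records at or
#' below each day, ending at 1.
#'
#' @inheritParams tto_summary
#' @return Tibble with columns `drugname`, `days`, `cum_frac`.
#' @export
#' @examples
#' cumulative_onset(tibble::tibble(drugname = "X", days = c(5, 5, 10)))
cumulative_onset <- function(records) {
  stopifnot(all(c("drugname", "days") %in% names(records)))
  records |>
    group_by(.data$drugname) |>
    reframe({
      tab <- table(.data$days)
      tibble(
        days = as.numeric(names(tab)),
        cum_frac = as.numeric(cumsum(tab)) / sum(tab)
      )
    })
}
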
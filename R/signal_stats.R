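# Disproportionality statistics on 2x2 contingency tables.
#
# For one drug-event pair the table is
#
#                 target event   other events
#   target drug        a              b
#   other drugs        c              d
#
# and the four screening statistics are
#
#   ROR  = ad / bc,          95% CI = exp(ln ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))
#   PRR  = [a/(a+b)] / [c/(c+d)],
#          95% CI = exp(ln PRR +/- 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))
#   chi2 = (ad - bc)^2 (a+b+c+d) / [(a+b)(c+d)(a+c)(b+d)]   (no continuity corr.)
#   IC   = log2[ a N / ((a+c)(a+b)) ],  IC025 = IC - 2 SD(IC)
#   EBGM = a N / ((a+c)(a+b)) (the unshrunk observed-to-expected ratio),
#          EBGM05 = exp(ln EBGM - 1.96 sqrt(1/a+1/b+1/c+1/d))
#
# IC and EBGM are both the relative reporting ratio, so IC == log2(EBGM)
# holds exactly. Zero cells make a statistic undefined (NA); no
# Haldane-Anscombe 0.5 correction is applied by default.

unpack_table <- function(a, b, c, d) {
  if (is.data.frame(a)) {
    stopifnot(all(c("a", "b", "c", "d") %in% names(a)))
    t <- list(a = a$a, b = a$b, c = a$c, d = a$d)
  } else {
    t <- list(a = a, b = b, c = c, d = d)
  }
  # doubles: cell products overflow 32-bit integers on database-scale counts
  lapply(t, as.numeric)
}

# observed-to-expected relative reporting ratio shared by IC and EBGM
# (shared so the IC == log2(EBGM) identity holds to the last bit)
rel_report_ratio <- function(a, b, c, d) {
  n <- a + b + c + d
  (a * n) / ((a + c) * (a + b))
}

wald_se <- function(a, b, c, d) {
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
}

#' Reporting odds ratio with Wald 95% interval
#'
#' `ROR = ad/bc`. Undefined cells (zero `b` or `c` for the point estimate;
#' any zero cell for the interval) yield `NA` rather than an error; no
#' continuity correction is applied.
#'
#' @param a,b,c,d Cell counts (vectors), or a data frame with columns
#'   `a`, `b`, `c`, `d` passed as the first argument.
#' @return Tibble with columns `ror`, `ror_lo`, `ror_hi`.
#' @export
#' @examples
#' compute_ror(10, 20, 30, 40)
compute_ror <- function(a, b = NULL, c = NULL, d = NULL) {
  t <- unpack_table(a, b, c, d)
  est <- ifelse(t$b > 0 & t$c > 0, (t$a * t$d) / (t$b * t$c), NA_real_)
  se <- wald_se(t$a, t$b, t$c, t$d)
  tibble(
    ror = est,
    ror_lo = est * exp(-1.96 * se),
    ror_hi = est * exp(1.96 * se)
  )
}

#' Proportional reporting ratio, Wald 95% interval, and Pearson chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-square is the uncorrected Pearson
#' statistic of the 2x2 table. Undefined quantities yield `NA`.
#'
#' @inheritParams compute_ror
#' @return Tibble with columns `prr`, `prr_lo`, `prr_hi`, `chi2`.
#' @export
#' @examples
#' compute_prr(20, 80, 80, 820)
compute_prr <- function(a, b = NULL, c = NULL, d = NULL) {
  t <- unpack_table(a, b, c, d)
  n <- t$a + t$b + t$c + t$d
  est <- ifelse((t$a + t$b) > 0 & t$c > 0 & (t$c + t$d) > 0,
                (t$a / (t$a + t$b)) / (t$c / (t$c + t$d)), NA_real_)
  se_ok <- t$a > 0 & t$c > 0 & (t$a + t$b) > 0 & (t$c + t$d) > 0
  se <- ifelse(se_ok,
               sqrt(1 / t$a - 1 / (t$a + t$b) + 1 / t$c - 1 / (t$c + t$d)),
               NA_real_)
  den <- (t$a + t$b) * (t$c + t$d) * (t$a + t$c) * (t$b + t$d)
  chi2 <- ifelse(den > 0, (t$a * t$d - t$b * t$c)^2 * n / den, NA_real_)
  tibble(
    prr = est,
    prr_lo = est * exp(-1.96 * se),
    prr_hi = est * exp(1.96 * se),
    chi2 = chi2
  )
}

#' Standard deviation of the information component
#'
#' The default closed form `SD(IC) = 1/(ln 2 * sqrt(a + 1))` depends on the
#' observed pair count only; it is the package's inferred dispersion for the
#' `IC - 2 SD > 0` screening criterion (see the methods vignette for its
#' calibration). The `"bate"` method is the closed-form posterior
#' approximation of the original BCPNN (Bate et al. 1998, with priors
#' alpha1 = beta1 = 1, alpha = beta = 2, gamma11 = 1) and needs the full
#' table.
#'
#' @inheritParams compute_ror
#' @param sd_method `"count"` (default) or `"bate"`.
#' @return Numeric vector of SDs in bits.
#' @export
bcpnn_sd <- function(a, b = NULL, c = NULL, d = NULL,
                     sd_method = c("count", "bate")) {
  sd_method <- match.arg(sd_method)
  t <- unpack_table(a, b, c, d)
  if (sd_method == "count") {
    return(1 / (log(2) * sqrt(t$a + 1)))
  }
  if (is.null(t$b) || is.null(t$c) || is.null(t$d)) {
    stop("sd_method = 'bate' needs the full contingency table", call. = FALSE)
  }
  n <- t$a + t$b + t$c + t$d
  n1. <- t$a + t$b
  n.1 <- t$a + t$c
  alpha1 <- 1; beta1 <- 1; alpha <- 2; beta <- 2; gamma11 <- 1
  gamma <- gamma11 * (n + alpha) * (n + beta) / ((n1. + alpha1) * (n.1 + beta1))
  v <- (n - t$a + gamma - gamma11) / ((t$a + gamma11) * (1 + n + gamma)) +
    (n - n1. + alpha - alpha1) / ((n1. + alpha1) * (1 + n + alpha)) +
    (n - n.1 + beta - beta1) / ((n.1 + beta1) * (1 + n + beta))
  sqrt(v) / log(2)
}

#' BCPNN information component and its lower screening bound
#'
#' `IC = log2[aN / ((a+c)(a+b))]` and `IC025 = IC - 2 SD(IC)` with the SD
#' from [bcpnn_sd()]. `IC` equals `log2` of the [compute_ebgm()] point
#' estimate on the same table, exactly.
#'
#' @inheritParams compute_ror
#' @inheritParams bcpnn_sd
#' @return Tibble with columns `ic`, `ic025` (bits).
#' @export
#' @examples
#' compute_ic(56, 2600, 1400, 2500000)
compute_ic <- function(a, b = NULL, c = NULL, d = NULL,
                       sd_method = c("count", "bate")) {
  sd_method <- match.arg(sd_method)
  t <- unpack_table(a, b, c, d)
  rr <- rel_report_ratio(t$a, t$b, t$c, t$d)
  ic <- ifelse(t$a > 0, log2(rr), NA_real_)
  sd_ic <- bcpnn_sd(t$a, t$b, t$c, t$d, sd_method = sd_method)
  tibble(ic = ic, ic025 = ic - 2 * sd_ic)
}

#' Observed-to-expected reporting ratio (EBGM as screened) and lower bound
#'
#' The point estimate is the unshrunk relative reporting ratio
#' `aN/((a+c)(a+b))`; no gamma-Poisson shrinkage is applied (a full MGPS
#' prior fit is out of scope, and the screening identity
#' `IC = log2(EBGM)` only holds for the unshrunk ratio). `EBGM05` is the
#' Wald lower 95% bound on the log scale.
#'
#' @inheritParams compute_ror
#' @return Tibble with columns `ebgm`, `ebgm05`.
#' @export
#' @examples
#' compute_ebgm(10, 90, 100, 9900)
compute_ebgm <- function(a, b = NULL, c = NULL, d = NULL) {
  t <- unpack_table(a, b, c, d)
  rr <- rel_report_ratio(t$a, t$b, t$c, t$d)
  est <- ifelse(t$a > 0, rr, NA_real_)
  se <- wald_se(t$a, t$b, t$c, t$d)
  tibble(ebgm = est, ebgm05 = est * exp(-1.96 * se))
}

#' Signal criteria for the four screening algorithms
#'
#' Defaults follow the conventional joint screen: ROR positive when
#' `a >= 3` and the ROR CI lower bound exceeds 1; PRR positive when
#' `a >= 3`, the PRR CI lower bound exceeds 1 and `PRR >= 2`; BCPNN
#' positive when `IC025 > 0`; MGPS positive when `EBGM05 > 2`. A pair is a
#' signal when all four fire.
#'
#' @param min_a Minimum pair count gating the ROR and PRR flags.
#' @param ror_lower_gt,prr_lower_gt Lower-CI thresholds (exclusive).
#' @param prr_min Minimum PRR point estimate (inclusive).
#' @param ic_lower_gt IC025 threshold (exclusive).
#' @param ebgm05_gt EBGM05 threshold (exclusive).
#' @return A list of class `signal_criteria`.
#' @export
signal_criteria <- function(min_a = 3, ror_lower_gt = 1, prr_min = 2,
                            prr_lower_gt = 1, ic_lower_gt = 0, ebgm05_gt = 2) {
  crit <- list(min_a = min_a, ror_lower_gt = ror_lower_gt, prr_min = prr_min,
               prr_lower_gt = prr_lower_gt, ic_lower_gt = ic_lower_gt,
               ebgm05_gt = ebgm05_gt)
  if (!all(vapply(crit, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                  logical(1)))) {
    stop("all signal criteria must be finite scalars", call. = FALSE)
  }
  structure(crit, class = "signal_criteria")
}

#' Compute all four disproportionality statistics for a table of counts
#'
#' @param tables Data frame with columns `a`, `b`, `c`, `d` (and any id
#'   columns, which are preserved).
#' @inheritParams bcpnn_sd
#' @return The input with `ror`, `ror_lo`, `ror_hi`, `prr`, `prr_lo`,
#'   `prr_hi`, `chi2`, `ic`, `ic025`, `ebgm`, `ebgm05` columns appended.
#' @export
disproportionality <- function(tables, sd_method = c("count", "bate")) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
  bind_cols(
    as_tibble(tables),
    compute_ror(tables),
    compute_prr(tables),
    compute_ic(tables, sd_method = sd_method),
    compute_ebgm(tables)
  )
}

# threshold comparison where an undefined statistic never fires a flag
exceeds <- function(x, threshold) !is.na(x) & x > threshold

#' Apply the signal criteria to computed statistics
#'
#' Adds the per-algorithm flags `ror_pos`, `prr_pos`, `bcpnn_pos`,
#' `mgps_pos` and their conjunction `signal`. Undefined statistics (NA)
#' never fire a flag.
#'
#' @param x Data frame with columns `a`, `ror_lo`, `prr`, `prr_lo`, `ic025`,
#'   `ebgm05` (as produced by [disproportionality()]).
#' @param criteria A [signal_criteria()] object.
#' @return `x` with the five logical columns appended.
#' @export
evaluate_signals <- function(x, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  mutate(
    as_tibble(x),
    ror_pos = .data$a >= criteria$min_a & exceeds(.data$ror_lo, criteria$ror_lower_gt),
    prr_pos = .data$a >= criteria$min_a & exceeds(.data$prr_lo, criteria$prr_lower_gt) &
      !is.na(.data$prr) & .data$prr >= criteria$prr_min,
    bcpnn_pos = exceeds(.data$ic025, criteria$ic_lower_gt),
    mgps_pos = exceeds(.data$ebgm05, criteria$ebgm05_gt),
    signal = .data$ror_pos & .data$prr_pos & .data$bcpnn_pos & .data$mgps_pos
  )
}

#' Screen every drug against a target event
#'
#' The full pipeline step: count report-level marginals over the
#' deduplicated universe, build the per-drug 2x2 tables, compute the four
#' statistics, apply the signal criteria, and rank. One row per drug with
#' `a >= min_count`, sorted by `a` descending, then ROR descending, then
#' drug name (a reproducible frequency ordering).
#'
#' @inheritParams select_event_cases
#' @param criteria A [signal_criteria()] object.
#' @param min_count Minimum pair count for a drug to be listed (default 1).
#' @inheritParams bcpnn_sd
#' @return A tibble of class `faers_signals` with count, statistic and flag
#'   columns, plus attributes `n_total`, `n_event`, `criteria`, `pt_terms`.
#' @export
screen_event <- function(reports, event, criteria = signal_criteria(),
                         min_count = 1, sd_method = c("count", "bate")) {
  m <- count_marginals(reports, event)
  if (attr(m, "n_event") == 0L) {
    warning("no reports match the event definition; returning empty result",
            call. = FALSE)
  }
  res <- m |>
    contingency_tables() |>
    filter(.data$a >= min_count) |>
    disproportionality(sd_method = sd_method) |>
    evaluate_signals(criteria) |>
    arrange(desc(.data$a), desc(.data$ror), .data$drugname)
  structure(
    res,
    n_total = attr(m, "n_total"),
    n_event = attr(m, "n_event"),
    criteria = criteria,
    pt_terms = attr(m, "pt_terms"),
    class = c("faers_signals", class(res))
  )
}

fmt_or_dash <- function(fmt, ...) {
  args <- list(...)
  out <- do.call(sprintf, c(list(fmt), args))
  out[Reduce(`|`, lapply(args, is.na))] <- "-"
  out
}

#' Publication-style formatting of a screening result
#'
#' Renders the ranked screen as display strings: point estimates with their
#' interval bound(s) in parentheses, two decimals, `-` for undefined.
#'
#' @param x A `faers_signals` tibble from [screen_event()].
#' @return Tibble with character columns `Drug`, `Number`, `ROR (95% CI)`,
#'   `PRR (chi2)`, `EBGM (EBGM05)`, `IC (IC025)` and logical `Signal`.
#' @export
format_signal_table <- function(x) {
  stopifnot(inherits(x, "faers_signals"))
  tibble(
    Drug = x$drugname,
    Number = x$a,
    `ROR (95% CI)` = fmt_or_dash("%.2f (%.2f - %.2f)", x$ror, x$ror_lo, x$ror_hi),
    `PRR (chi2)` = fmt_or_dash("%.2f (%.2f)", x$prr, x$chi2),
    `EBGM (EBGM05)` = fmt_or_dash("%.2f (%.2f)", x$ebgm, x$ebgm05),
    `IC (IC025)` = fmt_or_dash("%.2f (%.2f)", x$ic, x$ic025),
    Signal = x$signal
  )
}

#' Forest-plot data for a screening result
#'
#' @param x A `faers_signals` tibble.
#' @param positive_only Keep only rows flagged as signals.
#' @return Tibble with `drugname`, `ror`, `ror_lo`, `ror_hi`, their log10
#'   positions, and `signal`.
#' @export
forest_data <- function(x, positive_only = FALSE) {
  stopifnot(inherits(x, "faers_signals"))
  out <- as_tibble(x) |>
    filter(!is.na(.data$ror_lo)) |>
    select("drugname", "ror", "ror_lo", "ror_hi", "signal") |>
    mutate(
      log10_ror = log10(.data$ror),
      log10_lo = log10(.data$ror_lo),
      log10_hi = log10(.data$ror_hi)
    )
  if (positive_only) out <- filter(out, .data$signal)
  out
}
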
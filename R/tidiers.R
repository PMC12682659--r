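# broom-style tidiers for the package's result classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

strip_to_tibble <- function(x, drop_attrs = character()) {
  out <- x
  class(out) <- c("tbl_df", "tbl", "data.frame")
  for (a in drop_attrs) attr(out, a) <- NULL
  out
}

#' Tidy a screening result
#'
#' @param x A `faers_signals` tibble.
#' @param ... Unused.
#' @return A plain tibble with the full-precision statistic columns.
#' @method tidy faers_signals
#' @export
tidy.faers_signals <- function(x, ...) {
  strip_to_tibble(x, c("n_total", "n_event", "criteria", "pt_terms"))
}

#' One-row summary of a screening result
#'
#' @param x A `faers_signals` tibble.
#' @param ... Unused.
#' @return Tibble with `n_total`, `n_event`, `n_drugs`, `n_signal`.
#' @method glance faers_signals
#' @export
glance.faers_signals <- function(x, ...) {
  tibble(
    n_total = attr(x, "n_total"),
    n_event = attr(x, "n_event"),
    n_drugs = nrow(x),
    n_signal = sum(x$signal, na.rm = TRUE)
  )
}

#' Tidy marginal counts
#'
#' @param x A `faers_marginals` object.
#' @param ... Unused.
#' @return Per-drug tibble with `n_total` and `n_event` repeated alongside.
#' @method tidy faers_marginals
#' @export
tidy.faers_marginals <- function(x, ...) {
  strip_to_tibble(x, c("n_total", "n_event", "pt_terms")) |>
    mutate(n_total = attr(x, "n_total"), n_event = attr(x, "n_event"))
}

#' One-row summary of marginal counts
#'
#' @param x A `faers_marginals` object.
#' @param ... Unused.
#' @return Tibble with `n_total`, `n_event`, `n_drugs`.
#' @method glance faers_marginals
#' @export
glance.faers_marginals <- function(x, ...) {
  tibble(n_total = attr(x, "n_total"), n_event = attr(x, "n_event"),
         n_drugs = nrow(x))
}

#' Tidy a time-to-onset summary
#'
#' @param x A `faers_tto` tibble.
#' @param ... Unused.
#' @return The quantile columns without the histogram list-column.
#' @method tidy faers_tto
#' @export
tidy.faers_tto <- function(x, ...) {
  strip_to_tibble(x) |> select(-"bins")
}

#' Tidy deduplication decisions
#'
#' @param x A `dedup_decisions` tibble.
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy dedup_decisions
#' @export
tidy.dedup_decisions <- function(x, ...) {
  strip_to_tibble(x)
}

#' One-row summary of deduplication decisions
#'
#' @param x A `dedup_decisions` tibble.
#' @param ... Unused.
#' @return Tibble with key, case, retained and deleted counts.
#' @method glance dedup_decisions
#' @export
glance.dedup_decisions <- function(x, ...) {
  tibble(
    n_keys = nrow(x),
    n_cases = n_distinct(x$caseid),
    n_retained = sum(x$retained),
    n_deleted = sum(!x$retained)
  )
}

#' Tidy a descriptive summary into one long table
#'
#' @param x A `faers_description` object from [describe_reports()].
#' @param ... Unused.
#' @return Tibble with columns `dimension`, `category`, `n`, `pct` (`NA`
#'   where the dimension reports counts only).
#' @method tidy faers_description
#' @export
tidy.faers_description <- function(x, ...) {
  pieces <- lapply(names(x), function(nm) {
    tb <- x[[nm]]
    cat_col <- setdiff(names(tb), c("n", "pct", "outc_cod"))[1]
    tibble(
      dimension = nm,
      category = as.character(tb[[cat_col]]),
      n = tb$n,
      pct = if ("pct" %in% names(tb)) tb$pct else NA_real_
    )
  })
  bind_rows(pieces)
}
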
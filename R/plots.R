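# ggplot2 visualisations for screening and onset results.

#' Forest plot of a screening result
#'
#' Reporting odds ratios with 95% Wald intervals on a log axis; drugs with
#' undefined intervals are dropped.
#'
#' @param object A `faers_signals` tibble from [screen_event()].
#' @param positive_only Plot only rows flagged as signals.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot faers_signals
#' @export
autoplot.faers_signals <- function(object, positive_only = FALSE, ...) {
  df <- forest_data(object, positive_only = positive_only)
  ggplot(df, aes(x = .data$ror, y = stats::reorder(.data$drugname, .data$ror))) +
    geom_pointrange(aes(xmin = .data$ror_lo, xmax = .data$ror_hi,
                        colour = .data$signal)) +
    geom_vline(xintercept = 1, linetype = 2) +
    scale_x_log10() +
    labs(x = "Reporting odds ratio (log scale)", y = NULL, colour = "Signal")
}

#' Onset-time histograms of a time-to-onset summary
#'
#' One 30-day-bin histogram panel per drug.
#'
#' @param object A `faers_tto` tibble from [tto_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot faers_tto
#' @export
autoplot.faers_tto <- function(object, ...) {
  df <- object |>
    select("drugname", "bins") |>
    tidyr::unnest("bins")
  ggplot(df, aes(x = .data$bin, y = .data$n)) +
    geom_col() +
    facet_wrap(~drugname) +
    labs(x = "Time to onset (days)", y = "Reports") +
    theme(axis.text.x = element_text(angle = 60, hjust = 1))
}

#' Cumulative onset (ECDF) plot
#'
#' @param cum A tibble from [cumulative_onset()].
#' @return A ggplot object.
#' @export
plot_cumulative_onset <- function(cum) {
  stopifnot(all(c("drugname", "days", "cum_frac") %in% names(cum)))
  ggplot(cum, aes(x = .data$days, y = .data$cum_frac, colour = .data$drugname)) +
    geom_step() +
    labs(x = "Time to onset (days)", y = "Cumulative fraction of reports",
         colour = NULL)
}
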
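# In-code fixtures shared across the suite.

# compact builder for a faers_reports object from per-report specs:
# each report is list(pid, caseid=pid, fda=..., event_dt=..., drugs=list(
#   c(name, role) or c(name, role, start)), pts=c(...), outc=c(...))
make_reports <- function(...) {
  specs <- list(...)
  demo <- dplyr::bind_rows(lapply(specs, function(s) {
    tibble::tibble(
      primaryid = s$pid,
      caseid = s$caseid %||% s$pid,
      fda_dt = s$fda %||% 20240110,
      event_dt = s$event_dt %||% NA_real_,
      age = s$age %||% NA_real_,
      age_cod = s$age_cod %||% NA_character_,
      sex = s$sex %||% NA_character_,
      wt = s$wt %||% NA_real_,
      wt_cod = s$wt_cod %||% NA_character_,
      reporter_country = s$country %||% NA_character_,
      occp_cod = s$occp %||% NA_character_
    )
  }))
  drugs <- dplyr::bind_rows(lapply(specs, function(s) {
    if (is.null(s$drugs)) return(NULL)
    dplyr::bind_rows(lapply(seq_along(s$drugs), function(i) {
      d <- s$drugs[[i]]
      tibble::tibble(
        primaryid = s$pid, drug_seq = i, drugname = d[[1]], role_cod = d[[2]],
        start_dt = if (length(d) >= 3) as.numeric(d[[3]]) else NA_real_
      )
    }))
  }))
  reactions <- dplyr::bind_rows(lapply(specs, function(s) {
    if (is.null(s$pts)) return(NULL)
    tibble::tibble(primaryid = s$pid, pt = s$pts)
  }))
  outcomes <- dplyr::bind_rows(lapply(specs, function(s) {
    if (is.null(s$outc)) return(NULL)
    tibble::tibble(primaryid = s$pid, outc_cod = s$outc)
  }))
  if (nrow(drugs) == 0) drugs <- NULL
  args <- list(demo = demo)
  if (!is.null(drugs)) args$drugs <- drugs
  if (nrow(reactions) > 0) args$reactions <- reactions
  if (nrow(outcomes) > 0) args$outcomes <- outcomes
  do.call(faers_reports, args)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# brute-force deduplication oracle: sort each case group by (fda_dt,
# primaryid) and take the last element (missing fda_dt sorts first)
brute_dedup_retained <- function(keys) {
  sp <- split(keys, keys$caseid)
  sort(vapply(sp, function(g) {
    fda <- ifelse(is.na(g$fda_dt), -Inf, g$fda_dt)
    g$primaryid[order(fda, g$primaryid)][nrow(g)]
  }, numeric(1)), na.last = TRUE) |> unname()
}

# spiked-cohort config used by the parameter-recovery checks: one index
# drug at 5% exposure prevalence with multiplier `lambda`, 19 null drugs
# at 2%, baseline event reporting probability 0.2%
spiked_config <- function(lambda, n_reports, seed) {
  panel <- default_drug_panel()
  panel$lambda[1] <- lambda
  panel$marginal_prob[1] <- 0.05
  synth_config(
    n_reports = n_reports, drugs = panel, duplicate_rate = 0,
    missing_date_rate = 0, seed = seed
  )
}

target_pt_fixture <- "Polycystic ovaries"
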
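# Synthetic FAERS-quarter generator with full ground truth.
#
# The generator emulates the statistical structure the screening pipeline
# assumes: each report independently names each panel drug as primary
# suspect with its marginal probability; the probability that a report
# carries the target event PT is min(1, baseline_event_prob * lambda) where
# lambda is the largest association multiplier among its PS drugs (1 if
# none). Onset days for event reports are lognormal around the causal
# drug's configured median. Duplicate case versions share a caseid with
# equal-or-later receipt dates and higher primaryids.
#
# Reproducibility: every stage draws from its own seeded substream (a fixed
# offset of the configured seed), so adding draws to one stage never
# perturbs another. A fixed seed gives byte-identical output files.

default_decoy_pts <- c(
  "Headache", "Nausea", "Fatigue", "Dizziness", "Vomiting", "Rash",
  "Pruritus", "Insomnia", "Diarrhoea", "Weight increased", "Anxiety",
  "Alopecia", "Arthralgia", "Myalgia", "Abdominal pain", "Dyspnoea",
  "Somnolence", "Tremor", "Constipation", "Dry mouth", "Palpitations",
  "Hyperhidrosis", "Back pain", "Depression"
)

#' Default synthetic drug panel
#'
#' Twenty drugs, each named as primary suspect by 2% of reports, all null
#' (`lambda = 1`) with a 180-day median onset. Spiked scenarios are built
#' by editing rows of this tibble.
#'
#' @return Tibble with columns `name`, `marginal_prob`, `lambda`,
#'   `onset_median_days`.
#' @export
default_drug_panel <- function() {
  tibble(
    name = sprintf("DRUG%02d", seq_len(20)),
    marginal_prob = 0.02,
    lambda = 1,
    onset_median_days = 180
  )
}

sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * k) %% 2147483629)
}

#' Configuration for the synthetic FAERS-quarter generator
#'
#' @param n_reports Total number of distinct cases to generate.
#' @param drugs Drug panel tibble (`name`, `marginal_prob`, `lambda`,
#'   `onset_median_days`); see [default_drug_panel()].
#' @param baseline_event_prob Probability that a report with no associated
#'   PS drug carries the target event PT.
#' @param duplicate_rate Fraction of caseids emitted with more than one
#'   report version (in `[0, 1)`).
#' @param missing_date_rate Fraction of therapy start dates degraded (half
#'   set missing, half truncated to month precision).
#' @param onset_sigma Lognormal shape of the onset-day distribution.
#' @param target_pt Preferred term of the target event.
#' @param decoy_pts Pool of non-target preferred terms.
#' @param quarter_start,quarter_end `YYYYMMDD` bounds of the FDA receipt
#'   date window.
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_reports = 5000,
                         drugs = default_drug_panel(),
                         baseline_event_prob = 0.002,
                         duplicate_rate = 0.05,
                         missing_date_rate = 0.10,
                         onset_sigma = 1,
                         target_pt = "Polycystic ovaries",
                         decoy_pts = default_decoy_pts,
                         quarter_start = 20240101,
                         quarter_end = 20240331,
                         seed = 1L) {
  drugs <- as_tibble(drugs)
  stopifnot(
    n_reports >= 1,
    all(c("name", "marginal_prob", "lambda") %in% names(drugs)),
    nrow(drugs) >= 1
  )
  if (!"onset_median_days" %in% names(drugs)) drugs$onset_median_days <- 180
  probs <- c(drugs$marginal_prob, baseline_event_prob, duplicate_rate,
             missing_date_rate)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (duplicate_rate >= 1) stop("duplicate_rate must be < 1", call. = FALSE)
  if (any(drugs$lambda <= 0)) stop("lambda must be positive", call. = FALSE)
  if (anyDuplicated(normalize_drug_name(drugs$name))) {
    stop("drug panel names must be distinct after normalization", call. = FALSE)
  }
  if (is.na(int_to_date(quarter_start)) || is.na(int_to_date(quarter_end)) ||
      quarter_start > quarter_end) {
    stop("quarter_start/quarter_end must be valid YYYYMMDD dates in order",
         call. = FALSE)
  }
  structure(
    list(n_reports = as.integer(n_reports), drugs = drugs,
         baseline_event_prob = baseline_event_prob,
         duplicate_rate = duplicate_rate,
         missing_date_rate = missing_date_rate,
         onset_sigma = onset_sigma, target_pt = target_pt,
         decoy_pts = decoy_pts, quarter_start = quarter_start,
         quarter_end = quarter_end, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Read a generator configuration from a YAML file
#'
#' Top-level keys mirror the [synth_config()] arguments; `drugs` is a list
#' of records with `name`, `marginal_prob`, `lambda` and optional
#' `onset_median_days`.
#'
#' @param path Path to a YAML file.
#' @return A `synth_config` object.
#' @export
read_synth_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$drugs)) {
    y$drugs <- bind_rows(lapply(y$drugs, as_tibble))
  }
  do.call(synth_config, y)
}

# long (report row, drug index, role) vectors from the exposure matrices,
# sorted by report then drug index with a per-report entry sequence
exposure_long <- function(ps, conc, ss) {
  i_ps <- which(ps); i_c <- which(conc); i_ss <- which(ss)
  nr <- nrow(ps)
  row <- c((i_ps - 1L) %% nr, (i_c - 1L) %% nr, (i_ss - 1L) %% nr) + 1L
  k <- c((i_ps - 1L) %/% nr, (i_c - 1L) %/% nr, (i_ss - 1L) %/% nr) + 1L
  role <- rep(c("PS", "C", "SS"), c(length(i_ps), length(i_c), length(i_ss)))
  ord <- order(row, k)
  row <- row[ord]; k <- k[ord]; role <- role[ord]
  drug_seq <- sequence(rle(row)$lengths)
  list(row = row, k = k, role_cod = role, drug_seq = drug_seq)
}

#' Simulate an assembled report set with ground truth
#'
#' Draws one synthetic quarter at the report level and returns it already
#' assembled as a [faers_reports()] object, together with the ground truth
#' every pipeline stage can be checked against. [generate_quarter()] writes
#' the same draw out as the five ASCII files.
#'
#' @param cfg A [synth_config()].
#' @return A list with elements:
#'   * `reports`: a [faers_reports()] object (including any injected
#'     duplicate versions),
#'   * `truth`: list with `labels` (per-case `primaryid`, `caseid`, `event`,
#'     `causal_drug`), `ps_pairs`, `marginals` (realized report-level
#'     counts: `drugname`, `n_drug`, `n_drug_event`, with `n_total`,
#'     `n_event` attributes), `onset` (per causal pair: intended `days` and
#'     whether the dates survived degradation as `observable`), and
#'     `lineage` (per version: `caseid`, `primaryid`, `fda_dt`, `survivor`).
#' @export
simulate_reports <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_reports
  panel <- cfg$drugs
  K <- nrow(panel)
  drug_names <- normalize_drug_name(panel$name)

  # --- stream 1: keys and receipt dates
  set.seed(sub_seed(cfg$seed, 1))
  primaryid <- 100000000 + seq_len(n)
  caseid <- 50000000 + seq_len(n)
  qdays <- seq(int_to_date(cfg$quarter_start), int_to_date(cfg$quarter_end),
               by = "day")
  fda_date <- qdays[sample.int(length(qdays), n, replace = TRUE)]

  # --- stream 2: drug exposure (PS plus background SS/C roles)
  set.seed(sub_seed(cfg$seed, 2))
  ps <- matrix(runif(n * K), n, K) <
    matrix(panel$marginal_prob, n, K, byrow = TRUE)
  conc <- matrix(runif(n * K), n, K) < 0.01 & !ps
  ss <- matrix(runif(n * K), n, K) < 0.003 & !ps & !conc

  # --- stream 3: target event
  set.seed(sub_seed(cfg$seed, 3))
  lam <- rep(1, n)
  for (k in seq_len(K)) {
    lam[ps[, k]] <- pmax(lam[ps[, k]], panel$lambda[k])
  }
  event <- runif(n) < pmin(1, cfg$baseline_event_prob * lam)
  lam_mat <- sweep(ps * 1, 2, panel$lambda, `*`)
  has_ps <- rowSums(ps) > 0
  causal_idx <- rep(NA_integer_, n)
  causal_idx[has_ps] <- max.col(lam_mat[has_ps, , drop = FALSE],
                                ties.method = "first")

  # --- stream 4: event dates and intended onsets
  set.seed(sub_seed(cfg$seed, 4))
  delay <- sample(0:60, n, replace = TRUE)      # reporting delay
  event_date <- fda_date - delay                # event_dt <= fda_dt
  med <- panel$onset_median_days[causal_idx]
  med[is.na(med)] <- 180
  onset <- pmax(0, round(rlnorm(n, meanlog = log(med), sdlog = cfg$onset_sigma)))

  # --- stream 5: drug entry table with therapy starts
  set.seed(sub_seed(cfg$seed, 5))
  dl <- exposure_long(ps, conc, ss)
  n_dl <- length(dl$row)
  causal_row <- !is.na(causal_idx[dl$row]) & causal_idx[dl$row] == dl$k &
    event[dl$row] & dl$role_cod == "PS"
  other_gap <- pmax(0, round(rlnorm(n_dl, meanlog = log(180), sdlog = 1)))
  gap <- ifelse(causal_row, onset[dl$row], other_gap)
  start_date <- event_date[dl$row] - gap
  start_int <- date_to_int(start_date)
  u <- runif(n_dl)
  degraded <- u < cfg$missing_date_rate
  start_int[u < cfg$missing_date_rate / 2] <- NA_integer_
  partial <- degraded & !(u < cfg$missing_date_rate / 2)
  start_int[partial] <- start_int[partial] %/% 100  # truncate to YYYYMM

  # --- stream 6: demographics
  set.seed(sub_seed(cfg$seed, 6))
  age <- pmin(70, pmax(12, round(rnorm(n, 32, 12))))
  age[runif(n) < 0.08] <- NA
  age_cod <- ifelse(is.na(age), NA_character_, "YR")
  sex <- sample(c("F", "M", NA), n, replace = TRUE, prob = c(0.92, 0.05, 0.03))
  wt <- round(pmin(140, pmax(40, rnorm(n, 75, 20))), 1)
  lbs <- runif(n) < 0.05
  wt_cod <- ifelse(lbs, "LBS", "KG")
  wt[lbs] <- round(wt[lbs] / 0.453592, 1)
  wt_na <- runif(n) < 0.30
  wt[wt_na] <- NA
  wt_cod[wt_na] <- NA_character_
  country <- sample(c("US", "CA", "GB", "FR", "JP", "DE", "AU", "BR"),
                    n, replace = TRUE,
                    prob = c(0.55, 0.10, 0.08, 0.06, 0.05, 0.06, 0.05, 0.05))
  occp <- sample(c("CN", "MD", "OT", "PH", "LW", NA), n, replace = TRUE,
                 prob = c(0.50, 0.21, 0.10, 0.12, 0.03, 0.04))

  # --- stream 7: outcomes (a report may carry several codes)
  set.seed(sub_seed(cfg$seed, 7))
  out_codes <- c("OT", "HO", "DS", "LT", "DE", "CA", "RI")
  out_prob <- c(0.45, 0.28, 0.08, 0.06, 0.05, 0.03, 0.05)
  first <- sample(out_codes, n, replace = TRUE, prob = out_prob)
  second_draw <- sample(out_codes, n, replace = TRUE, prob = out_prob)
  has_second <- runif(n) < 0.25 & second_draw != first
  outc <- tibble(
    primaryid = c(primaryid, primaryid[has_second]),
    outc_cod = c(first, second_draw[has_second])
  ) |>
    arrange(.data$primaryid)

  # --- stream 8: reactions
  set.seed(sub_seed(cfg$seed, 8))
  n_decoy <- ifelse(event, rpois(n, 0.7), 1L + rpois(n, 0.8))
  decoy_pid <- rep(primaryid, n_decoy)
  decoys <- sample(cfg$decoy_pts, sum(n_decoy), replace = TRUE)
  reac <- bind_rows(
    tibble(primaryid = primaryid[event], pt = cfg$target_pt),
    tibble(primaryid = decoy_pid, pt = decoys)
  ) |>
    distinct(.data$primaryid, .data$pt) |>
    arrange(.data$primaryid, .data$pt)

  demo <- tibble(
    primaryid = primaryid, caseid = caseid,
    fda_dt = date_to_int(fda_date), event_dt = date_to_int(event_date),
    age = age, age_cod = age_cod, sex = sex, wt = wt, wt_cod = wt_cod,
    reporter_country = country, occp_cod = occp
  )
  drugs_tbl <- tibble(
    primaryid = primaryid[dl$row],
    drug_seq = dl$drug_seq,
    drugname = drug_names[dl$k],
    role_cod = dl$role_cod,
    start_dt = as.numeric(start_int)
  )
  reports <- faers_reports(demo, drugs_tbl, reac, outc)

  # --- stream 9: duplicate versions
  dup <- inject_duplicates(reports, cfg$duplicate_rate,
                           seed = sub_seed(cfg$seed, 9))

  ps_pairs <- tibble(
    primaryid = primaryid[dl$row[dl$role_cod == "PS"]],
    drugname = drug_names[dl$k[dl$role_cod == "PS"]]
  ) |> arrange(.data$primaryid, .data$drugname)
  marginals <- tibble(
    drugname = drug_names,
    n_drug = colSums(ps),
    n_drug_event = colSums(ps & event)
  )
  attr(marginals, "n_total") <- n
  attr(marginals, "n_event") <- sum(event)

  causal_pair <- which(causal_row)
  onset_truth <- tibble(
    primaryid = primaryid[dl$row[causal_pair]],
    drugname = drug_names[dl$k[causal_pair]],
    days = onset[dl$row[causal_pair]],
    observable = !degraded[causal_pair]
  )

  labels <- tibble(
    primaryid = primaryid, caseid = caseid, event = event,
    causal_drug = ifelse(event & !is.na(causal_idx),
                         drug_names[causal_idx], NA_character_)
  )

  list(
    reports = dup$reports,
    truth = list(
      labels = labels,
      ps_pairs = ps_pairs,
      marginals = marginals,
      onset = onset_truth,
      lineage = dup$lineage,
      config = cfg
    )
  )
}

#' Inject duplicate report versions
#'
#' A fraction of cases gains 1-3 extra versions sharing the caseid, with
#' equal-or-later FDA receipt dates and strictly higher primaryids; child
#' table rows are copied under the new primaryid. The intended survivor per
#' affected case (lexicographic maximum on `(fda_dt, primaryid)`, computed
#' independently of [deduplicate()]) is recorded in the returned lineage.
#'
#' @param reports A [faers_reports()] object with one version per case.
#' @param rate Fraction of cases to duplicate, in `[0, 1)`.
#' @param seed Integer seed for the duplication draws.
#' @return A list with `reports` (versions appended) and `lineage` (tibble
#'   of `caseid`, `primaryid`, `fda_dt`, `survivor` covering every version
#'   of every duplicated case; empty when `rate = 0`).
#' @export
inject_duplicates <- function(reports, rate, seed = 1L) {
  stopifnot(inherits(reports, "faers_reports"), rate >= 0, rate < 1)
  empty_lineage <- tibble(caseid = numeric(), primaryid = numeric(),
                          fda_dt = numeric(), survivor = logical())
  if (rate == 0) {
    return(list(reports = reports, lineage = empty_lineage))
  }
  set.seed(seed)
  demo <- reports$demo
  n <- nrow(demo)
  sel <- which(runif(n) < rate)
  if (length(sel) == 0L) {
    return(list(reports = reports, lineage = empty_lineage))
  }
  k_extra <- sample(1:3, length(sel), replace = TRUE)
  idx <- rep(sel, k_extra)
  new_pid <- max(demo$primaryid) + seq_along(idx)
  add_days <- sample(0:90, length(idx), replace = TRUE)
  new_fda <- date_to_int(int_to_date(demo$fda_dt[idx]) + add_days)

  new_demo <- demo[idx, ]
  new_demo$primaryid <- new_pid
  new_demo$fda_dt <- as.numeric(new_fda)

  map <- tibble(primaryid = demo$primaryid[idx], new_pid = new_pid)
  copy_children <- function(tbl) {
    dup_rows <- inner_join(tbl, map, by = "primaryid",
                           relationship = "many-to-many") |>
      mutate(primaryid = .data$new_pid) |>
      select(-"new_pid")
    bind_rows(tbl, dup_rows)
  }

  out <- faers_reports(
    demo = bind_rows(demo, new_demo),
    drugs = copy_children(reports$drugs),
    reactions = copy_children(reports$reactions),
    outcomes = copy_children(reports$outcomes)
  )

  lineage <- bind_rows(
    tibble(caseid = demo$caseid[sel], primaryid = demo$primaryid[sel],
           fda_dt = demo$fda_dt[sel]),
    tibble(caseid = demo$caseid[idx], primaryid = new_pid,
           fda_dt = as.numeric(new_fda))
  ) |>
    group_by(.data$caseid) |>
    mutate(survivor = {
      ord <- order(.data$fda_dt, .data$primaryid)
      s <- rep(FALSE, length(ord))
      s[ord[length(ord)]] <- TRUE
      s
    }) |>
    ungroup() |>
    arrange(.data$caseid, .data$primaryid)

  list(reports = out, lineage = lineage)
}

#' Write a synthetic quarter as FAERS ASCII files
#'
#' Runs [simulate_reports()] and writes the draw as the five `$`-delimited
#' files (`DEMO.txt`, `DRUG.txt`, `REAC.txt`, `THER.txt`, `OUTC.txt`) plus
#' two tab-delimited ground-truth files (`TRUTH_LABELS.txt`,
#' `TRUTH_LINEAGE.txt`). A fixed seed yields byte-identical files.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `files` (named paths), `truth` and
#'   `reports` as from [simulate_reports()].
#' @export
generate_quarter <- function(cfg, dir) {
  sim <- simulate_reports(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  r <- sim$reports
  ther <- r$drugs |>
    filter(!is.na(.data$start_dt)) |>
    transmute(primaryid = .data$primaryid, dsg_drug_seq = .data$drug_seq,
              start_dt = .data$start_dt)
  files <- c(
    DEMO = file.path(dir, "DEMO.txt"),
    DRUG = file.path(dir, "DRUG.txt"),
    REAC = file.path(dir, "REAC.txt"),
    THER = file.path(dir, "THER.txt"),
    OUTC = file.path(dir, "OUTC.txt"),
    TRUTH_LABELS = file.path(dir, "TRUTH_LABELS.txt"),
    TRUTH_LINEAGE = file.path(dir, "TRUTH_LINEAGE.txt")
  )
  write_faers_table(r$demo, files[["DEMO"]])
  write_faers_table(select(r$drugs, -"start_dt"), files[["DRUG"]])
  write_faers_table(r$reactions, files[["REAC"]])
  write_faers_table(ther, files[["THER"]])
  write_faers_table(r$outcomes, files[["OUTC"]])
  write.table(sim$truth$labels, files[["TRUTH_LABELS"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$lineage, files[["TRUTH_LINEAGE"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(files = files, truth = sim$truth, reports = sim$reports))
}
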
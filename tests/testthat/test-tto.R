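test_that("onset day arithmetic and exclusion reasons are correct", {
  od <- onset_days(
    c(20200101, 20200301, 202001, 20200230, NA, 20200101),
    c(20200131, 20200101, 20200301, 20200301, 20200301, 20200101)
  )
  expect_equal(od$days, c(30L, NA, NA, NA, NA, 0L))
  expect_equal(od$status,
               c("ok", "negative", "partial", "invalid", "missing", "ok"))
})

test_that("day differences agree with an independent calendar oracle", {
  set.seed(300)
  base <- as.Date("2010-01-01")
  d1 <- base + sample(0:6000, 1000, replace = TRUE)
  d2 <- base + sample(0:6000, 1000, replace = TRUE)
  od <- onset_days(date_to_int(d1), date_to_int(d2))
  expected <- as.integer(lubridate::ymd(sprintf("%08d", date_to_int(d2))) -
                           lubridate::ymd(sprintf("%08d", date_to_int(d1))))
  expected[expected < 0] <- NA_integer_
  expect_equal(od$days, expected)
  expect_true(all(od$status[is.na(expected)] == "negative"))
})

test_that("quantiles interpolate between order statistics", {
  s <- tto_summary(tibble::tibble(drugname = "X", days = c(10, 20, 30, 40)))
  expect_equal(s$q1, 17.5)
  expect_equal(s$median, 25.0)
  expect_equal(s$q3, 32.5)
  s1 <- tto_summary(tibble::tibble(drugname = "X", days = 7))
  expect_equal(c(s1$q1, s1$median, s1$q3), c(7, 7, 7))
  expect_true(all(s$q1 <= s$median & s$median <= s$q3))
})

test_that("onset bins follow the 30-day boundary convention", {
  b <- bin_onsets(c(0, 30, 31, 360, 361))
  expect_equal(b$n[b$bin == "0-30"], 2L)
  expect_equal(b$n[b$bin == "31-60"], 1L)
  expect_equal(b$n[b$bin == "331-360"], 1L)
  expect_equal(b$n[b$bin == ">360"], 1L)
  expect_equal(sum(b$n), 5L)
  expect_equal(sum(bin_onsets(integer(0))$n), 0L)
  set.seed(301)
  days <- sample(0:2000, 137, replace = TRUE)
  expect_equal(sum(bin_onsets(days)$n), 137L)
})

test_that("the empirical cumulative onset curve is a proper ECDF", {
  cum <- cumulative_onset(tibble::tibble(drugname = "X", days = c(5, 5, 10)))
  expect_equal(cum$days, c(5, 10))
  expect_equal(cum$cum_frac, c(2 / 3, 1))
  set.seed(302)
  rec <- tibble::tibble(drugname = rep(c("A", "B"), each = 80),
                        days = sample(0:900, 160, replace = TRUE))
  cum2 <- cumulative_onset(rec)
  for (d in c("A", "B")) {
    cc <- cum2[cum2$drugname == d, ]
    expect_true(all(diff(cc$cum_frac) > 0))
    expect_equal(cc$cum_frac[nrow(cc)], 1)
  }
})

test_that("ECDF, bins and quantiles are mutually consistent", {
  set.seed(303)
  rec <- tibble::tibble(drugname = "A", days = sample(0:700, 90, replace = TRUE))
  s <- tto_summary(rec)
  cum <- cumulative_onset(rec)
  # cumulative fraction at the median is at least one half
  expect_gte(max(cum$cum_frac[cum$days <= s$median]), 0.5)
  # cumulative fraction at day 30 equals the first bin share
  bins <- s$bins[[1]]
  at30 <- c(0, cum$cum_frac[cum$days <= 30])
  expect_equal(max(at30), bins$n[bins$bin == "0-30"] / s$n)
})

test_that("onset records use the earliest full-precision start per drug", {
  rep <- make_reports(
    list(pid = 1, event_dt = 20240301, pts = "Polycystic ovaries",
         drugs = list(c("X", "PS", 20240201), c("X", "PS", 20240101),
                      c("X", "PS", 202312))),     # partial start ignored
    list(pid = 2, event_dt = 20240301, pts = "Polycystic ovaries",
         drugs = list(c("Y", "PS", 202401))),     # only partial -> excluded
    list(pid = 3, event_dt = 20240301, pts = "Polycystic ovaries",
         drugs = list(c("Z", "PS", 20240401))),   # negative -> excluded
    list(pid = 4, event_dt = 20240301, pts = "Headache",
         drugs = list(c("X", "PS", 20240101)))    # not an event case
  )
  rec <- tto_records(rep, "Polycystic ovaries")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$days, 60L)
  excl <- attr(rec, "excluded")
  expect_equal(sort(excl$status), c("negative", "partial"))
  # drug restriction is normalized
  expect_equal(nrow(tto_records(rep, "Polycystic ovaries", drugs = " x ")), 1)
})

test_that("onset summaries recover the generator's intended days", {
  cfg <- synth_config(n_reports = 4000, duplicate_rate = 0,
                      missing_date_rate = 0, seed = 71,
                      drugs = dplyr::mutate(default_drug_panel(),
                                            lambda = ifelse(name == "DRUG01", 30, 1),
                                            marginal_prob = ifelse(name == "DRUG01", 0.08, 0.02)))
  sim <- simulate_reports(cfg)
  rec <- tto_records(sim$reports, target_pt_fixture, drugs = "DRUG01")
  truth <- sim$truth$onset |>
    dplyr::filter(drugname == "DRUG01", observable)
  joined <- dplyr::inner_join(rec, truth, by = c("primaryid", "drugname"))
  expect_equal(nrow(joined), nrow(rec))
  expect_equal(joined$days.x, joined$days.y)
})
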
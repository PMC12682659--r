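test_that("closed-form statistics match frozen hand calculations", {
  # ROR on (10, 20, 30, 40): 10*40/(20*30); Wald CI half-width
  # 1.96*sqrt(1/10+1/20+1/30+1/40)
  r <- compute_ror(10, 20, 30, 40)
  expect_equal(r$ror, 0.6666667, tolerance = 1e-6)
  expect_equal(r$ror_lo, 0.272510, tolerance = 1e-5)
  expect_equal(r$ror_hi, 1.630927, tolerance = 1e-5)
  # ROR on (10, 90, 100, 9900) = 11
  expect_equal(compute_ror(10, 90, 100, 9900)$ror, 11)
  # PRR on (10, 20, 30, 40) = (10/30)/(30/70)
  p <- compute_prr(10, 20, 30, 40)
  expect_equal(p$prr, 0.7777778, tolerance = 1e-6)
  expect_equal(p$prr_lo, 0.438172, tolerance = 1e-5)
  expect_equal(p$prr_hi, 1.380595, tolerance = 1e-5)
  # chi-square on (20, 80, 80, 820) = (20*820-80*80)^2*1000/(100*900*100*900)
  expect_equal(compute_prr(20, 80, 80, 820)$chi2, 12.345679, tolerance = 1e-6)
  # EBGM on (10, 90, 100, 9900) = 10*10100/(110*100)
  expect_equal(compute_ebgm(10, 90, 100, 9900)$ebgm, 9.181818, tolerance = 1e-6)
})

test_that("independence tables sit at the null values", {
  r <- compute_ror(10, 10, 10, 10)
  expect_equal(r$ror, 1)
  expect_lt(r$ror_lo, 1)
  expect_gt(r$ror_hi, 1)
  p <- compute_prr(10, 10, 10, 10)
  expect_equal(p$prr, 1)
  expect_equal(p$chi2, 0)
  expect_equal(compute_ic(10, 10, 10, 10)$ic, 0)
  expect_equal(compute_ebgm(10, 10, 10, 10)$ebgm, 1)
  # any table with ad = bc has chi2 = 0
  expect_equal(compute_prr(6, 9, 10, 15)$chi2, 0)
})

test_that("IC equals log2(EBGM) to machine precision on random tables", {
  set.seed(77)
  tbl <- tibble::tibble(
    a = sample(1:500, 300, replace = TRUE),
    b = sample(1:5000, 300, replace = TRUE),
    c = sample(1:5000, 300, replace = TRUE),
    d = sample(1:100000, 300, replace = TRUE)
  )
  expect_identical(compute_ic(tbl)$ic, log2(compute_ebgm(tbl)$ebgm))
})

test_that("ROR dominates PRR whenever ROR exceeds 1", {
  set.seed(78)
  tbl <- tibble::tibble(
    a = sample(1:200, 500, replace = TRUE),
    b = sample(1:2000, 500, replace = TRUE),
    c = sample(1:2000, 500, replace = TRUE),
    d = sample(1:50000, 500, replace = TRUE)
  )
  ror <- compute_ror(tbl)$ror
  prr <- compute_prr(tbl)$prr
  above <- ror > 1
  expect_true(all(ror[above] >= prr[above]))
})

test_that("all four statistics increase strictly in a with b, c, d fixed", {
  a <- 1:60
  s <- disproportionality(tibble::tibble(a = a, b = 500, c = 300, d = 40000))
  expect_true(all(diff(s$ror) > 0))
  expect_true(all(diff(s$prr) > 0))
  expect_true(all(diff(s$ic) > 0))
  expect_true(all(diff(s$ebgm) > 0))
})

test_that("chi-square is invariant under transposing the table", {
  set.seed(79)
  for (i in 1:20) {
    t <- sample(1:1000, 4)
    expect_equal(compute_prr(t[1], t[2], t[3], t[4])$chi2,
                 compute_prr(t[1], t[3], t[2], t[4])$chi2)
  }
})

test_that("Wald CI coverage of the true odds ratio is near nominal under the null", {
  set.seed(80)
  n1 <- 2000; n0 <- 48000; p <- 0.005
  a <- rbinom(500, n1, p); c <- rbinom(500, n0, p)
  r <- compute_ror(tibble::tibble(a = a, b = n1 - a, c = c, d = n0 - c))
  covered <- !is.na(r$ror_lo) & r$ror_lo <= 1 & r$ror_hi >= 1
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
  # point estimates concentrate on the null value as counts grow
  big <- compute_ror(tibble::tibble(a = rbinom(1, 2e5, p), b = 2e5,
                                    c = rbinom(1, 2e6, p), d = 2e6))
  expect_equal(big$ror, 1, tolerance = 0.1)
})

test_that("signal flags equal a brute-force re-evaluation of the criteria", {
  crit <- signal_criteria()
  grid <- expand.grid(a = c(1, 2, 3, 5, 20, 60), b = c(5, 60),
                      c = c(5, 60), d = c(500, 20000))
  s <- evaluate_signals(disproportionality(grid), crit)
  expect_equal(s$ror_pos,
               s$a >= 3 & !is.na(s$ror_lo) & s$ror_lo > 1)
  expect_equal(s$prr_pos,
               s$a >= 3 & !is.na(s$prr_lo) & s$prr_lo > 1 &
                 !is.na(s$prr) & s$prr >= 2)
  expect_equal(s$bcpnn_pos, !is.na(s$ic025) & s$ic025 > 0)
  expect_equal(s$mgps_pos, !is.na(s$ebgm05) & s$ebgm05 > 2)
  expect_equal(s$signal, s$ror_pos & s$prr_pos & s$bcpnn_pos & s$mgps_pos)
})

test_that("the minimum-count gate blocks tiny-count ROR/PRR flags", {
  # a = 2 with an enormous ROR still fails the count gate
  s <- evaluate_signals(disproportionality(
    tibble::tibble(a = 2, b = 1, c = 5, d = 50000)))
  expect_false(s$ror_pos)
  expect_false(s$prr_pos)
  expect_false(s$signal)
})

test_that("zero cells yield flagged-undefined results, never errors or signals", {
  s <- evaluate_signals(disproportionality(
    tibble::tibble(a = c(5, 0), b = c(0, 10), c = c(0, 8), d = c(100, 100))))
  expect_true(is.na(s$ror[1]))          # zero b: point estimate undefined
  expect_equal(s$ror[2], 0)             # zero a: defined but null-bounded
  expect_true(all(is.na(s$ror_lo)))     # intervals need all cells positive
  expect_true(all(is.na(s$ic[2])))
  expect_false(any(s$signal))
  # single-drug universe: every event case names the drug, c = 0
  rep <- make_reports(
    list(pid = 1, pts = "Polycystic ovaries", drugs = list(c("X", "PS"))),
    list(pid = 2, pts = "Headache", drugs = list(c("X", "PS")))
  )
  sig <- screen_event(rep, "Polycystic ovaries")
  expect_equal(nrow(sig), 1)
  expect_true(is.na(sig$ror))
  expect_false(sig$signal)
})

test_that("the Bate posterior SD is a sane alternative dispersion", {
  tbl <- tibble::tibble(a = c(4, 20, 100), b = 500, c = 300, d = 40000)
  sd_b <- bcpnn_sd(tbl, sd_method = "bate")
  expect_true(all(is.finite(sd_b) & sd_b > 0))
  expect_true(all(diff(sd_b) < 0))  # shrinks as the pair count grows
  ic <- compute_ic(tbl, sd_method = "bate")
  expect_true(all(ic$ic025 < ic$ic))
})

test_that("screening output is ranked, reproducible, and formatted cleanly", {
  cfg <- spiked_config(lambda = 8, n_reports = 20000, seed = 55)
  rep <- simulate_reports(cfg)$reports
  s1 <- screen_event(rep, target_pt_fixture)
  s2 <- screen_event(rep, target_pt_fixture)
  expect_identical(tidy(s1), tidy(s2))
  expect_true(all(diff(s1$a) <= 0))
  expect_equal(glance(s1)$n_total, 20000)
  ft <- format_signal_table(s1)
  expect_match(ft$`ROR (95% CI)`[1], "^[0-9.]+ \\([0-9.]+ - [0-9.]+\\)$")
  fd <- forest_data(s1)
  expect_true(all(c("log10_ror", "log10_lo", "log10_hi") %in% names(fd)))
  expect_s3_class(autoplot(s1), "ggplot")
})

test_that("screening an event with no cases warns and returns empty", {
  rep <- make_reports(list(pid = 1, pts = "Headache",
                           drugs = list(c("X", "PS"))))
  expect_warning(s <- screen_event(rep, "Absent term"), "no reports")
  expect_equal(nrow(s), 0)
})
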
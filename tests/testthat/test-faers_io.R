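test_that("a minimal well-formed DEMO file parses with no quarantine", {
  path <- withr::local_tempfile()
  writeLines(c("primaryid$caseid$fda_dt",
               "101$11$20240101",
               "102$12$20240102"), path)
  tbl <- read_faers_table(path, "DEMO")
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$primaryid, c(101, 102))
  expect_equal(tbl$fda_dt, c(20240101, 20240102))
  pr <- parse_report(tbl)
  expect_equal(pr$n_rows, 2)
  expect_equal(pr$n_quarantined, 0)
  # absent demographic columns are auto-filled, not an error
  expect_true(all(c("event_dt", "age", "sex") %in% names(tbl)))
  expect_true(all(is.na(tbl$age)))
})

test_that("a line with an embedded extra delimiter is quarantined, not dropped", {
  path <- withr::local_tempfile()
  writeLines(c("primaryid$pt",
               "101$Headache",
               "102$Rash$odd",
               "103$Nausea"), path)
  tbl <- read_faers_table(path, "REAC")
  expect_equal(nrow(tbl), 2)
  pr <- parse_report(tbl)
  expect_equal(pr$n_quarantined, 1)
  expect_equal(pr$quarantined$line, 3L)
  expect_equal(pr$quarantined$content, "102$Rash$odd")
})

test_that("trailing empty fields survive the split", {
  path <- withr::local_tempfile()
  writeLines(c("primaryid$caseid$fda_dt$occp_cod", "101$11$20240101$"), path)
  tbl <- read_faers_table(path, "DEMO")
  expect_equal(nrow(tbl), 1)
  expect_true(is.na(tbl$occp_cod))
})

test_that("a header missing a key column is a schema error naming it", {
  path <- withr::local_tempfile()
  writeLines(c("caseid$fda_dt", "11$20240101"), path)
  expect_error(read_faers_table(path, "DEMO"), "primaryid")
  expect_error(read_faers_table("/nonexistent/DEMO.txt", "DEMO"), "not found")
})

test_that("a generated quarter round-trips value-identically", {
  cfg <- synth_config(n_reports = 400, duplicate_rate = 0.2,
                      missing_date_rate = 0.2, seed = 42)
  dir <- withr::local_tempdir()
  gen <- generate_quarter(cfg, dir)
  q_raw <- read_faers_quarter(dir)
  for (k in c("demo", "drug", "reac", "ther", "outc")) {
    expect_equal(parse_report(q_raw[[k]])$n_quarantined, 0)
  }
  q <- lapply(q_raw, function(tb) {
    attr(tb, "parse_report") <- NULL
    tb
  })
  r <- gen$reports
  expect_equal(as.data.frame(q$demo), as.data.frame(r$demo))
  expect_equal(as.data.frame(q$drug),
               as.data.frame(dplyr::select(r$drugs, -start_dt)))
  expect_equal(as.data.frame(q$reac), as.data.frame(r$reactions))
  expect_equal(as.data.frame(q$outc), as.data.frame(r$outcomes))
  ther_expected <- r$drugs |>
    dplyr::filter(!is.na(start_dt)) |>
    dplyr::transmute(primaryid, dsg_drug_seq = drug_seq, start_dt)
  expect_equal(as.data.frame(q$ther), as.data.frame(ther_expected))
})

test_that("assembly joins child tables by primaryid and counts orphans", {
  demo <- tibble::tibble(primaryid = 1, caseid = 10, fda_dt = 20240101)
  drug <- tibble::tibble(primaryid = c(1, 1), drug_seq = c(1, 2),
                         drugname = c("olanzapine ", "METFORMIN"),
                         role_cod = c("PS", "C"))
  reac <- tibble::tibble(primaryid = c(1, 99), pt = c("Headache", "Rash"))
  ther <- tibble::tibble(primaryid = 1, dsg_drug_seq = 1, start_dt = 20230101)
  rep <- assemble_reports(demo, drug, reac, ther)
  expect_equal(n_reports(rep), 1)
  expect_equal(nrow(rep$drugs), 2)
  expect_equal(rep$drugs$drugname, c("OLANZAPINE", "METFORMIN"))
  expect_equal(rep$drugs$start_dt, c(20230101, NA))
  expect_equal(nrow(rep$reactions), 1)
  expect_equal(attr(rep, "orphans")[["reac"]], 1L)
})

test_that("duplicate primaryid in DEMO is rejected unless tolerated", {
  demo <- tibble::tibble(primaryid = c(1, 1), caseid = c(10, 10),
                         fda_dt = c(20240101, 20240102))
  reac <- tibble::tibble(primaryid = 1, pt = "Headache")
  drug <- tibble::tibble(primaryid = numeric(), drug_seq = numeric(),
                         drugname = character(), role_cod = character())
  expect_error(assemble_reports(demo, drug, reac), "duplicate primaryid")
  rep <- assemble_reports(demo, drug, reac, tolerate_duplicates = TRUE)
  expect_equal(n_reports(rep), 2)
})

test_that("unknown drug role codes are rejected at construction", {
  demo <- tibble::tibble(primaryid = 1, caseid = 1, fda_dt = 20240101)
  drugs <- tibble::tibble(primaryid = 1, drug_seq = 1, drugname = "X",
                          role_cod = "ZZ")
  expect_error(faers_reports(demo, drugs), "role code")
})

test_that("reaction rows are conserved through assembly", {
  cfg <- synth_config(n_reports = 300, duplicate_rate = 0, seed = 5)
  dir <- withr::local_tempdir()
  generate_quarter(cfg, dir)
  q <- read_faers_quarter(dir)
  rep <- assemble_reports(q$demo, q$drug, q$reac, q$ther, q$outc)
  expect_equal(nrow(rep$reactions),
               sum(q$reac$primaryid %in% q$demo$primaryid))
})
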
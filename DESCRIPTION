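Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance toolkit for FDA Adverse Event
    Reporting System (FAERS) style spontaneous-report data: ingestion of the
    quarterly dollar-delimited ASCII extracts (DEMO, DRUG, REAC, THER, OUTC),
    case deduplication by the latest-receipt-date / highest-report-version
    rule, MedDRA preferred-term case selection restricted to primary-suspect
    drugs, four disproportionality statistics (reporting odds ratio,
    proportional reporting ratio with Pearson chi-square, BCPNN information
    component, and the observed-to-expected ratio used by MGPS-style
    screening) with their conventional signal criteria, time-to-onset
    quantile and cumulative-incidence summaries, and descriptive reporting.
    A seeded synthetic FAERS-quarter generator with full ground truth makes
    every stage testable without downloading real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    lubridate,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
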
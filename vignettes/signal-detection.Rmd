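---
title: "Disproportionality signal detection for spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for spontaneous reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem and the data model

Spontaneous-report databases such as FAERS collect voluntary safety reports:
one report names a patient, one or more drugs (each with a role code — primary
suspect, secondary suspect, concomitant, interacting), one or more adverse
events coded as MedDRA preferred terms (PTs), therapy dates, and outcome
codes. Reports arrive as quarterly `$`-delimited ASCII tables keyed by
`primaryid` (a report *version*) and `caseid` (a *case* that may accumulate
several versions over time).

`faersignal` treats a quarter (or a concatenation of quarters) as a relational
object: one DEMO row per report version plus child tables of drug entries,
reactions and outcomes. The unit of every count downstream is the
*deduplicated report*, never the drug–reaction line.

## Deduplication

Within each `caseid`, the retained version is the lexicographic maximum on
`(fda_dt, primaryid)`: the latest FDA receipt date, ties broken by the highest
report-version identifier. The rule is deliberately key-based; probabilistic
record linkage across manufacturers (matching on age, sex and dates) is a
different problem and out of scope. A version with missing `fda_dt` sorts as
earliest, so it is only retained when it is the case's sole version, and the
parser warns about it. The decision table (`deduplicate()`) records a reason
per version (`only_version`, `latest_fda_dt`, `highest_primaryid`,
`superseded`) and exports as a Yes/No audit log (`write_dedup_audit()`).

Deduplication runs on keys *before* any joins: `assemble_reports()` treats a
duplicated `primaryid` in DEMO as an error unless explicitly tolerated, and
`dedup_reports()` filters every child table to the retained versions.

## Case selection and counting

An event definition is a list of PT strings; matching is exact after case
folding. No MedDRA hierarchy traversal or SMQ expansion is attempted — the
term list must spell out every PT of interest. This keeps the selection
auditable and independent of a licensed dictionary.

Exposure is restricted to primary-suspect entries. Counts are report-level:

- `n_total` (N) — all deduplicated reports in the window, including reports
  with no PS drug at all; the `d` cell needs the full universe.
- `n_event` (a + c) — reports carrying any target PT.
- per drug: `n_drug` (a + b) — reports naming the drug as PS, counted once
  per report however many times the entry repeats; `n_drug_event` (a).

Non-event reports contribute to `b` through their PS drugs under the same
role filter, by symmetry of the 2×2 layout.

## The four statistics

With cells a, b, c, d and N = a + b + c + d:

- **ROR** = ad/bc with the Wald interval
  exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d)).
- **PRR** = [a/(a+b)]/[c/(c+d)] with interval
  exp(ln PRR ± 1.96·√(1/a − 1/(a+b) + 1/c − 1/(c+d))) and the *uncorrected*
  Pearson χ² = (ad − bc)²·N / [(a+b)(c+d)(a+c)(b+d)]. No Yates continuity
  correction is applied anywhere.
- **IC** = log₂[aN/((a+c)(a+b))], the BCPNN information component.
- **EBGM** = aN/((a+c)(a+b)) with EBGM05 = exp(ln EBGM − 1.96·√(1/a + 1/b +
  1/c + 1/d)).

Two deliberate design points:

**EBGM without shrinkage.** The screened quantity is the raw
observed-to-expected ratio, not a gamma–Poisson posterior mean. Published
screening tables in this tradition satisfy IC = log₂(EBGM) row by row, which
only holds for the unshrunk ratio; `faersignal` therefore shares one
expression between `compute_ic()` and `compute_ebgm()` so the identity holds
to the last bit, and a genuine MGPS prior fit is explicitly out of scope.
Interpret EBGM05 accordingly: it is a Wald bound on the ratio, not a
shrinkage-calibrated EB05.

**The IC dispersion.** The screening criterion is IC − 2·SD > 0, but the SD
convention in published tables is frequently unstated. The package's default
is the count-based closed form SD(IC) = 1/(ln 2·√(a + 1)). This form was
chosen because it reconstructs published (IC, IC025) pairs across pair counts
from 4 to 56 to within ±0.01 after rounding — the acceptance suite performs
exactly that reconstruction. It is documented as inferred, and the
closed-form posterior variance of the original BCPNN (Bate et al. 1998, with
priors α₁ = β₁ = 1, α = β = 2, γ₁₁ = 1) is available via
`compute_ic(sd_method = "bate")` for users who want the Bayesian dispersion.

**Zero cells.** No Haldane–Anscombe 0.5 correction is applied by default: a
zero cell yields an `NA` statistic carrying through to a `FALSE` flag, never
an error and never a silent correction. In the degenerate single-drug
universe (c = 0) the screen returns an undefined row rather than crashing.

**Criteria and ranking.** Flags: ROR positive ⇔ a ≥ 3 and ROR CI lower
bound > 1; PRR positive ⇔ a ≥ 3, PRR CI lower bound > 1 and PRR ≥ 2; BCPNN
positive ⇔ IC025 > 0; MGPS positive ⇔ EBGM05 > 2; signal ⇔ all four. All
thresholds are configurable through `signal_criteria()`. Output is ranked by
pair count descending, then ROR descending, then drug name — a reproducible
frequency ordering. No multiple-testing adjustment is applied (none is
conventional in this screen); all four flags are exported so users can
post-filter.

## Time to onset

Latency is the calendar-day difference from therapy start to the event date.
Which date pair defines latency is genuinely underdetermined in spontaneous
reports; the package's documented default is the DEMO `event_dt` minus the
*earliest full-precision* therapy start among the report's PS entries for the
drug — the conservative exposure origin. Partial dates (`YYYYMM`, `YYYY`)
are retained by the parser but excluded from day-resolution arithmetic;
negative differences are excluded; each exclusion is counted by reason.
Day-0 onsets are kept (a start on the event date is bin 0–30).

Quantiles use linear interpolation between order statistics (position
h = (n − 1)·p, R's type-7 default). This convention is what produces
fractional published values such as medians ending in .50 or quartiles in
.75, which cannot arise under nearest-rank quantiles. Histograms use fixed
30-day bins with day 30 in 0–30, day 31 in 31–60, and an open >360 bin; the
ECDF at day 30 equals the first bin's share by construction, and the tests
assert that cross-consistency.

## The synthetic-data generator

Real FAERS quarters cannot be redistributed with the package, and published
screening tables depend on the full 2014–2024 database; the generator
instead emulates the *statistical structure* the pipeline assumes, with
complete ground truth:

- each report names each panel drug as PS independently with its
  `marginal_prob` (default panel: 20 drugs at 2%), plus background
  concomitant (1%) and secondary-suspect (0.3%) roles so the role filter is
  exercised;
- the target-event probability is min(1, `baseline_event_prob` · λ) where λ
  is the largest multiplier among the report's PS drugs (1 when none).
  The default baseline reporting probability is 0.2% — a rare-event PT
  against a pool of 24 decoy PTs, so the b and d cells are well populated;
- onset days for event reports are lognormal with the causal drug's
  configured median (scale = ln median) and shape σ = 1 by default;
  `event_dt` ≤ `fda_dt` is enforced, receipt dates fall in the configured
  quarter window;
- `missing_date_rate` degrades therapy starts only (half to missing, half
  truncated to month precision), keeping the exclusion paths of the onset
  module active while demographics stay complete;
- `duplicate_rate` gives a fraction of cases 1–3 extra versions with
  equal-or-later receipt dates and higher primaryids; the intended survivor
  is recorded by an independent order-based scan so deduplication can be
  checked against lineage truth;
- every stage draws from its own fixed-offset substream of the seed, so a
  fixed seed yields byte-identical files and adding draws to one stage never
  perturbs another.

What the generator does *not* emulate: drug-name misspellings and free-text
dosage, real reporting-delay structure, correlated polypharmacy, indication
channeling, or secular trends across years. Passing tests therefore
demonstrate that the machinery is correct under the declared model, not that
real-data confounding (notably indication bias) is handled — no
disproportionality screen handles it.

## Study conditions used by the tests

The simulation-based checks run at sizes chosen to balance Monte-Carlo error
against desk-scale runtimes:

- parameter recovery: 50,000-report cohorts, one index drug at 5% exposure
  prevalence spiked at λ ∈ {2, 5, 20} (expected pair counts ≈ 10/25/100),
  19 null drugs at 2%, 200 seeded replicates per λ. The Wald ROR interval is
  expected to cover λ at close to its nominal 95% (the residual odds-vs-risk
  gap at λ = 20 is ~4% of the estimate, small against the interval width),
  the full four-criteria gate should fire essentially always at λ = 20, and
  null drugs should pass the joint gate well under 1% of the time;
- onset recovery: ~500 onset records with a configured 900-day median
  (relative sampling error of the lognormal median at σ = 1 is ≈ 5.6%);
- oracle equivalence: 1,000 randomized key sets against a brute-force
  group-sort deduplication oracle, closed-form grids for ROR/PRR/χ², and
  ECDF/bin/quantile cross-checks on random inputs.

## Known limitations

- Drug names are normalized only by case and whitespace; brand/generic
  harmonization and ingredient mapping belong to an external vocabulary and
  are intentionally not guessed at.
- The EBGM column is the unshrunk ratio (see above); small-count rows are
  noisier than a fitted MGPS would report.
- Event matching is literal PT equality; a study using an SMQ must expand
  the term list itself.
- XML-format ingestion, INDI/RPSR tables and stratified (age/sex/year)
  analyses are not implemented.
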
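---
title: "Cleaning electronic-monitor adherence data: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning electronic-monitor adherence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhclean)
```

## The measurement model

An electronic monitor (EM) registers the date and time of every opening
of a pill container; each opening is taken as a proxy for one medication
intake. The quantity of interest is *implementation*: on each day of the
monitoring window, did the patient's (corrected) openings meet the
regimen's expectation? Formally, for monitor $m$ on day $t$:

$$y(m,t) = \mathbf{1}\{c(m,t) \ge e(m,t)\}, \qquad
  c(m,t) = \max\{0,\, r(m,t) + a(m,t)\},$$

where $e$ is the expected openings per day under the regimen in force,
$r$ the recorded openings, and $a$ the net documented correction for
that day. On days inside a declared nonmonitored period $y$ is not
calculated at all. The patient-level daily value is the product of
$y(m,t)$ over all monitors whose window covers $t$, with `NA`
propagating: one suboptimal monitor makes the patient day suboptimal,
one censored monitor censors the patient day. Implementation *rates*
are optimal days over monitored days.

Three consequences of the $\ge$ rule deserve emphasis, because they are
behavioural commitments of the whole package:

* **overconsumption is not penalised** — 3 openings against 1 expected
  is optimal;
* **Off-cycle days are trivially optimal** — $0 \ge 0$ — and they stay
  in the denominator, which mechanically raises rates under cyclic
  regimens relative to an On-days-only denominator;
* **censoring only removes days** — it never alters corrected counts on
  the remaining days, so a rate can move in either direction when a
  censoring interval is added (the removed days may have been optimal
  or suboptimal).

## Inputs and the validation contract

Two inputs drive the calculation. The raw EM exports (filenames
containing `eventslist`) are one row per opening — `PatientCode`,
`Monitor`, `Date` — or, in the pre-aggregated *dailyadherence* form,
one row per day with a `RecordedOpenings` count. The Auxiliary Data
workbook carries the investigator's knowledge: monitoring windows
(`EMInfo`), regimen periods (`Regimen`, with `On`/`Off` day counts for
cyclic schemes), signed opening corrections (`AddedOpenings`),
censoring intervals (`NonMonitoredPeriods`), free-form covariables at
patient and monitor level, and descriptive adverse events. Sheet and
column names are case-sensitive.

Findings are split into **critical errors**, which would corrupt the
calculation and therefore block all output (unparseable or ambiguous
dates, missing mandatory sheets/columns/values, an `On` without an
`Off`, auxiliary rows referencing undeclared monitors, regimen coverage
gaps or overlaps inside a window), and **warnings**, which flag
inconsistencies for review but never block (declared monitors without
raw data, raw data for undeclared monitors — excluded from output —,
censoring intervals clipped to the window, corrections clamped at
zero). Both are always written to `errors.log` / `warnings.log` in a
deterministic order.

Two interval conventions matter enough to state explicitly. All date
intervals are **closed on both ends**: a window `2021-01-01..2021-01-10`
has 10 days. And every day of every monitoring window must be covered by
**exactly one** regimen period; a gap is a critical error rather than an
implicit "expected 0", because a silent zero would count untreated days
as optimal and inflate every rate.

## Schedules and cyclic regimens

A regimen row expands to per-day expected counts. A continuous row is a
constant; a cyclic row repeats `On` days at `ExpectedOpenings` followed
by `Off` days at zero. The cycle phase is anchored at the **regimen
row's own start date**, not the monitoring window's: a 21/7 period that
began before the window keeps its phase, and a regimen change mid-cycle
simply starts a new period with a fresh anchor. Alternate-day two-bottle
schemes (two dosage strengths on alternating days) are represented as
two monitors with `On = 1, Off = 1` periods whose start dates are offset
by one day. Schedules are truncated to the monitoring window on both
sides.

## Corrections and censoring

Corrections are *documented facts*, not inferences: the package never
guesses pocket doses, curiosity checks or nonuse periods from opening
patterns, because those events must be patient-reported and validated
(e.g. by pill count) before they belong in the data. A positive
`AddedOpenings` delta inserts pocket doses; a negative one removes
extra openings; deltas for the same day are summed and the corrected
count floors at zero with a warning (an over-deletion is a curatorial
mistake the investigator must see, but not one worth aborting the run).
When a day is both censored and adjusted, censoring wins: the
adjustment is retained in the ledger but implementation stays empty.
Doses prepared in advance for the following day are handled by the
investigator declaring that day nonmonitored; the pipeline deliberately
provides no automation of that judgement.

The "raw" (before-cleaning) implementation used in before/after
comparisons is defined as the identical calculus with adjustments and
censoring disabled while schedules and window truncation still apply —
the workbook's structural knowledge is part of the design, not of the
cleaning.

## The synthetic study generator

`simulate_adherence()` creates a full study — event files, auxiliary
workbook, and the true per-day implementation — with every injected
deviation recorded both as a perturbation of the raw events and as the
corresponding auxiliary row, so full cleaning recovers the truth
exactly. The intake process is deliberately minimal: each scheduled
dose is taken independently with the patient's probability $p$; taken
doses bypass the EM (pocket dose) with a fixed probability; extra
openings arrive as at most one per day; nonmonitored intervals arrive
at a fixed rate per 100 days with uniform lengths, and deviations are
never generated inside them so the ground truth stays unambiguous.

The default configuration is a miniature oncology cohort chosen once as
realistic for this setting: 10 patients, 5 of them with two EMs (15
monitors), log-normal monitoring durations with median 187 days, one
21/7 cyclic monitor, one alternate-day two-EM pair, one mid-window
regimen change, per-patient intake probabilities Beta(60, 2.5) (mean
0.96), 4% pocket doses, 2% daily extra openings, and 0.8 nonmonitored
intervals per 100 days of 3–14 days. Under these conditions the median
patient implementation is in the mid-90s after cleaning and roughly 15
percentage points lower before cleaning — the qualitative raw-vs-clean
gap that motivates the whole exercise.

What the generator does **not** emulate: intake timing within the day
(only daily counts matter here), dose strengths, correlated day-to-day
adherence (no habit or weekend structure), undocumented deviations
(every deviation is perfectly documented, which is exactly what makes
exact recovery a meaningful test of the plumbing rather than a claim
about real-world completeness of documentation), and monitor
malfunction. Passing the recovery tests therefore shows the pipeline
computes the defined statistic correctly, not that real EM data can
always be cleaned to truth.

## Numerical and testing choices

All computations are exact integer/date arithmetic; there are no
tolerances to tune. Verification rests on three independent routes: a
brute-force day-by-day oracle (plain loops over the sheet rows,
sharing no code with the vectorised pipeline) compared on dozens of
randomized small fixtures (up to 5 patients, 3 monitors, 60-day
windows); exact recovery of the generator's truth across many seeds;
and a parameter-recovery check in which 200 simulated patients over 100
days at known intake probability $p \in \{0.6, 0.8, 0.95\}$ must
reproduce $p$ within two Monte-Carlo standard errors. These sizes keep
the full suite in single-digit minutes while leaving the Monte-Carlo
error well below the effects being checked.

The workbook writer embedded in the package produces minimal
SpreadsheetML with uncompressed archive entries — one sheet per table,
inline strings, dates as ISO 8601 text, `NA` as genuinely empty cells —
which makes outputs byte-reproducible for a fixed input and keeps the
nonmonitored-day "empty cell" convention honest (a censored day is not
a 0 and not the text `"NA"`).

## Known limitations

* Timing adherence (intervals between openings, same-day timing pocket
  doses) is out of scope; corrections are per-day counts.
* Persistence analysis (time to discontinuation) and longitudinal
  modelling of the daily binary outcome are downstream of this package.
* Ambiguous text dates (`03/04/2021`) are rejected rather than guessed;
  data exported with locale-specific date formats must be normalised
  first.
* The patient-day scope is restricted to monitors whose window covers
  the date; staggered windows therefore contribute only where they
  overlap, and a patient's denominator is the union of their windows.
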
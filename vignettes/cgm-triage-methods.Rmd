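---
title: "Methods: consensus CGM metrics, flag rules, and the synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus CGM metrics, flag rules, and the synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmtriage)
```

## Scope and model

`cgmtriage` screens a clinical population of CGM wearers for deteriorating
glucose control. The model is deliberately rule-based rather than
statistical: care teams need to explain *why* a patient was flagged, and a
threshold on a consensus metric ("mean glucose above 170 mg/dL", "time in
range fell more than 10 points below this patient's own baseline") is
directly actionable in a way a model score is not. The package therefore
contains no fitted parameters; everything it computes is a deterministic
function of the readings, the window definitions and the configured
thresholds.

## Canonical series and ingestion

All analysis operates on a canonical per-patient series: strictly
time-ordered readings in mg/dL with a nominal sampling interval of 5 or 15
minutes. Ingestion decisions that the data sources leave open are resolved
as follows:

* **Units.** mg/dL is canonical; mmol/L is converted with the molar-mass
  factor 18.0182 and rounded to one decimal (sensor displays carry no more
  precision).
* **Duplicate timestamps.** The first-seen value in file order wins, after
  a stable sort. This is deterministic and makes ingestion idempotent and
  invariant to row shuffling; device exports occasionally repeat rows on
  re-download, and no principled basis exists for preferring the later
  value.
* **Timezones.** Timestamps are naive local clinic time. Daylight-saving
  transitions are not adjusted: review windows are wall-clock constructs
  ("the week ending Sunday"), and re-zoning readings would move them across
  day boundaries the clinic does not experience.
* **Interval inference.** The median of successive timestamp differences,
  snapped to the nearer of 5 or 15 minutes (midpoint toward 5). The median
  is robust to wear gaps, which appear as a few large differences.

## Windows

Three day segments follow the consensus convention: whole day
[00:00, 24:00), daytime [06:00, 24:00), nighttime [00:00, 06:00). All
clock and period windows are half-open so that the segments partition the
day exactly and a reading stamped at midnight belongs to the nighttime of
the new day; whole-day counts always equal daytime plus nighttime counts.

Three weekly review conventions are supported. The clinic default,
`week_ending_sunday`, is the Monday-to-Sunday week whose Sunday is the last
one *strictly before* the review date, so a Sunday review still looks at a
complete prior week. `trailing_7_days` serves ad-hoc reviews, and
`week_starting_sunday` (the last full Sunday-to-Saturday week) is the
longitudinal-evaluation convention, chosen so that every patient's weekly
windows align across a cohort regardless of when their sensor started.

## Metrics

For a window with $n_{\text{possible}}$ nominal sampling slots and $n$
valid readings: ACT $= 100\,n/n_{\text{possible}}$; MG is the mean;
TIR/Hyp/eHyp/TAR classify each reading against 70–180 (inclusive), <70,
<54 and >180 mg/dL. Making TIR inclusive on both ends and Hyp/TAR strict
ensures {Hyp, TIR, TAR} is an exact partition — the package asserts
TIR + Hyp + TAR = 100 as an invariant. When a window holds no readings,
the glucose-derived metrics are explicit `NA` markers rather than zeros:
flag evaluation must distinguish "no data" (a separate triage tab) from
"in range", and a zero TIR would silently flag an absent patient.

Both a reading-level wear percentage (`act_pct`) and a day count
(`days_active`, days meeting the valid-day rule) are exposed, because
clinical practice quotes wear in both forms and conflating them loses
information. `n_possible` uses the patient's own nominal interval so
15-minute sensors are not penalized relative to 5-minute ones.

The **valid-day rule** (for cohort analyses) includes a calendar day when
at least 70% of its sampling slots hold a reading; the comparison is `>=`
(at 5 minutes: 202 of 288 readings pass, 201 fail).

## Flags

All comparators are strict — a metric exactly at its threshold never
triggers — matching how the thresholds are written (">170", "<60%").
Generic rules never fire on `NA` metrics. Personalized rules exist for MG
(rise of more than 10 mg/dL over baseline) and TIR (drop of more than 10
percentage points), and are evaluated only for patients with at least
`min_history_weeks` (default 4) weeks of data before the review period;
with less history no personalized flag is ever emitted.

Two presets reflect the two settings the thresholds serve:

* `clinic`: TIR < 60%, eHyp > 1%, Hyp > 4%, a wear annotation at
  ACT < 75%, personalized TIR drop vs a 4-week baseline, weeks ending
  Sunday. The wear rule is deliberately an *annotation*, not an alert: low
  sensor wear prompts a conversation about sensor supply, not a glucose
  intervention, and promoting it to the alerts tab would erode the tab's
  meaning.
* `simulation`: MG > 170, TIR < 60%, eHyp > 1%, Hyp > 3%, personalized
  MG +10 / TIR −10 vs the single preceding week, Sunday-starting weeks.

The baseline length differs between presets (4 weeks vs 1) because the two
settings pose different questions: the clinic compares a week against a
month of the patient's recent norm, while the longitudinal evaluation asks
for week-over-week deterioration. Both are expressible through
`baseline_spec()`; the 4-week *eligibility* requirement is shared so the
generic and personalized columns of a cohort evaluation describe the same
patients.

## Population report

One row per patient per review; tabs partition the population into
`alerts` / `no_data` / `no_alerts`. Rows sort alerts-first, then by
descending mean glucose (a severity proxy), ties broken by patient id for
determinism. The *reduction in patients reviewed* is the share of the
population not flagged; patients with no data count as unreviewed by
default — a no-data week prompts outreach about wear, not a data review —
and this is configurable because other clinics may handle it differently.
The HTML rendering is a static page in which only flag-triggering cells
carry a highlight class.

## Longitudinal cohort evaluation

The evaluation unit is the *eligible patient-week*: after valid-day
filtering, a Sunday-aligned week containing at least one included day.
This denominator choice is the package's own (rates need a denominator and
"weeks with any usable data" is the least arbitrary); personalized-rate
denominators additionally require an evaluable baseline window, so they
can never exceed the generic denominators. Cross-patient medians, IQRs and
SDs of per-patient rates summarize the distribution; the paired two-tailed
*t* test on per-patient generic-minus-personalized rate differences uses
the classical closed form and reports "undefined" for degenerate inputs
(fewer than two pairs or zero-variance differences) rather than a spurious
statistic.

Confusion summaries cross-tabulate flag outcomes against reference labels,
excluding insufficient-data reviews from the 2×2 table while still
counting them. Published screening tables often print only rounded
percentages and N; `counts_from_percent()` reconstructs the integer counts
(`round(pct × N / 100)`) first and derives rates from those, which
reproduces printed derived rates exactly where direct percentage
arithmetic would not.

## The synthetic generator

`generate_patient()` simulates glucose as a stationary AR(1) process
around a per-patient target mean, clipped to the common CGM reportable
range 40–400 mg/dL, with whole days dropped independently to emulate
sensor wear gaps, and `inject_change()` adds a signed step shift from a
given onset. `generate_cohort()` draws target means from a truncated
normal and derives per-patient seeds deterministically from a master seed,
so cohorts are exactly reproducible while patients are independent.

The generator emulates the two axes of real populations that the flag
rules are sensitive to: large between-patient spread in mean glucose
(real data sets span roughly 141–207 mg/dL in cohort mean, which the
default `cohort_sd = 25` around 170 reproduces) and within-patient
week-to-week stability. Defaults: `within_sd = 55` mg/dL (a coefficient
of variation near 33%, typical of type 1 diabetes), `wear_prob = 0.9`
(about 6.3 active days per week, inside the 3.4–6.8 range seen across
real data sets), 5-minute sampling, and `phi = 0.7`. The autocorrelation
default is chosen for the *weekly-aggregate* behaviour the package
analyzes — with `phi = 0.7` and ~2000 readings per week, a stationary
patient's weekly MG has a standard error near 3 mg/dL, so week-over-week
changes rarely approach the 10 mg/dL personalized threshold, matching the
low personalized flag rates of stable real cohorts. Real 5-minute traces
are smoother (lag-one autocorrelation above 0.9), but reproducing trace
smoothness would inflate weekly variance beyond what stable cohorts show;
since no analysis in the package consumes sub-window dynamics, the
week-level calibration takes precedence. Meal and insulin dynamics,
sensor error models and compression artifacts are deliberately not
modeled — so passing tests demonstrate correct *bookkeeping and rule
logic* on realistic marginal statistics, not clinical validity on real
traces.

`oracle_label()` is an independent, deliberately naive reimplementation of
the triage decision (plain scans, literal thresholds, no shared code with
the metrics/flags modules). It exists so that end-to-end tests can score
the pipeline against reference truth that cannot share a bug with the
implementation.

## Validation problem sizes

The test suite validates the metric engine against a brute-force scan on
200 seeded patient-weeks (40 patients × 5 weeks, all three day segments);
the end-to-end recovery experiment uses a 100-patient cohort with 20
injected +25 mg/dL step changes in week 6 (detection sensitivity 100%
against the independent labeler under these conditions, since a 25 mg/dL
shift exceeds the 10 mg/dL personalized threshold by many weekly standard
errors); the dispersion contrast between generic and personalized TIR
rates uses a 60-patient cohort with between-patient SD 30 mg/dL. These
sizes give Monte-Carlo tolerances far smaller than the effects asserted
while keeping the suite fast.

## Known limitations

* Flags consider only the five consensus metrics; variability metrics
  (CV, SD bands), GMI and ambulatory glucose profiles are out of scope,
  though the rule registry accepts any metric the bundle exposes.
* The valid-day and eligibility conventions (70%, 4 weeks, week windows)
  are configurable but interact; comparisons across configurations should
  hold them fixed.
* Naive local time means a clinic spanning timezones, or data exported
  with zone offsets, must normalize before ingestion.
* The synthetic generator supports step changes only; gradual drift,
  periodic (weekday/weekend) structure and sensor noise are not modeled.
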
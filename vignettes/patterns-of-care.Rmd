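---
title: "Phase-of-care attribution of cancer-related health care: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-of-care attribution of cancer-related health care: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carepatterns)
```

## The problem

Cost-of-illness and patterns-of-care studies on administrative health data
must decide which hospitalizations, outpatient services and drug
prescriptions are attributable to a disease. Two broad designs exist: the
*matched-control* (indirect) design, which estimates incremental utilization
against a comparison cohort without the disease, and the *direct
(attribution)* design, which classifies an event as disease-related whenever
its code belongs to a clinician-drawn list of disease-related codes. The
direct design needs no comparison cohort — which population cancer
registries often cannot obtain — and is the method this package implements,
for the case of breast cancer: lists of ICD-9-CM procedure/diagnosis codes,
national outpatient codes and ATC drug codes (the *D-lists*), each code
carrying a clinical category and sub-category.

`carepatterns` covers the full analysis chain on registry data linked to
four administrative streams — hospital discharges (HD), outpatient services
(OPS), pharmacy-dispensed prescriptions (DP) and hospital-administered
high-cost drugs (HP) — plus a seeded synthetic-data generator used to
validate the chain end to end.

## Phases of care

The design is cross-sectional on a *prevalence date* (2011-01-01 in the
reference setting). Each woman alive on that date and diagnosed before it is
assigned to exactly one of three mutually exclusive phases:

* **initial** — diagnosed within the 12 months before the prevalence date
  and alive 12 months after it;
* **final** — dies of cancer within 12 months after the prevalence date,
  regardless of diagnosis date;
* **continuing** — diagnosed more than 12 months before and alive 12 months
  after.

Women dying of non-cancer causes in that year are censored: they belong to
no phase and contribute no events. Each non-censored patient then receives a
12-month observation window — from diagnosis forward (initial), from death
backward (final), or from 6 months before to 6 months after the prevalence
date (continuing).

Two conventions the source design leaves open are fixed here:

* **Half-open intervals everywhere.** "Within 12 months before" means
  `diagnosis >= prevalence - 12 months` and `< prevalence`; a death exactly
  12 months after the prevalence date is outside the final year; an event on
  `window_end` is outside the window. This avoids double counting at
  boundaries.
* **Calendar-month arithmetic.** "One year" is 12 calendar months
  (2010-06-15 + 12m = 2011-06-15, with end-of-month rollback), matching the
  "initial year" / "last year of life" phrasing rather than a fixed 365
  days. Month-only registry dates are imputed to day 15 with a warning.

## Attribution

An event is cancer-related iff its code belongs to the D-list of its stream,
after normalization (whitespace stripped, upper-cased, dots removed from
ICD-9-CM-based codes; ATC compared verbatim). Matching is exact: prefix
matching would silently widen the enumerated lists, so it is available only
as an explicit opt-in for ATC codes.

A hospital episode carries up to six diagnosis and six procedure codes and
is cancer-related if *any* of them is listed. For tabulation each episode
contributes one row, classified by its main cancer-related
intervention/procedure. Since no tie-break is prescribed when several codes
match, the default rule takes the **first match in slot order** — procedure
slots main to secondary, then diagnosis slots main to secondary — on the
grounds that slot 1 is the designated "main" code and procedures, when
present, define what the admission was for. A category-priority alternative
(Surgery > Chemotherapy > Radiotherapy > ...) is provided for sensitivity
analysis. Episodes are anchored on the admission date for window membership.
Outpatient and drug records contribute one row per record. HP events are
flagged and exported but never tabulated; that stream's coverage is too
uneven for quantitative use.

## Frequency tables and the phase-weighted distribution

Within-phase tables report absolute counts and percent distributions by
category/sub-category per phase, with percents computed in full precision
and rounded half away from zero to one decimal (matching published
formats; `round()`'s half-even rule would disagree on exact halves).
Outpatient codes flagged `excluded_from_frequency` (standard blood tests,
genetic markers) stay in the list but out of the tables: prescribed one
record per test, they would otherwise swamp the distribution. Prescription
tables carry categories only.

The published figure of category distributions "weighted by the percent
distribution of patients by phase of care" is ambiguous as stated. We adopt
the **per-patient rate normalization**: with count \(c_p\) and cohort size
\(n_p\) in phase \(p\),

\[ \text{share}_p = \frac{c_p / n_p}{\sum_q c_q / n_q} \times 100. \]

This interpretation reproduces all five shares printed alongside the figure
(surgery 91% initial; hospital radiotherapy 62%, chemotherapy 53% and
diagnostics 76% final; outpatient radiotherapy 80% initial) from the
published table counts and cohort sizes (7501 / 39,369 / 2400), which is the
justification for adopting it; the acceptance tests pin it down. Shares are
scale-invariant in the cohort sizes and sum to 100%.

The bundled reference tables ship as plain CSV. One printed cell
(continuing-phase analgesic prescriptions) is typographically corrupted in
the source; it is reconstructed as 12,450 — the unique value consistent with
every printed percentage of that column — and the garbled total rows are
recomputed as category sums. The printed outpatient continuing-phase share
"70%" is likewise inconsistent with its own counts (which give 69.3%); the
package reports exact arithmetic and documents the discrepancy rather than
matching the rounded figure.

## Self-control validation of the code lists

Patients diagnosed within the year before the prevalence date have
administrative coverage of their pre-diagnostic period, so they can serve as
their own controls. Each such patient contributes a 10-month **case** window
`[diagnosis, diagnosis + 10m)` and a 10-month **control** window
`[diagnosis - 12m, diagnosis - 2m)`; the two months immediately before
diagnosis are excluded from both, because diagnostic work-up there is
already cancer-driven. For every candidate code, per-patient occurrence
counts (explicit zeros included) in the two windows are compared with the
unequal-variance two-sample t-test using Satterthwaite's degrees of freedom:

\[ t = \frac{\bar x - \bar y}{\sqrt{s_x^2/n_x + s_y^2/n_y}},\qquad
   \nu = \frac{(s_x^2/n_x + s_y^2/n_y)^2}
              {\frac{(s_x^2/n_x)^2}{n_x-1} + \frac{(s_y^2/n_y)^2}{n_y-1}}. \]

Codes with two-sided \(p < 0.05\) form the empirical *C-list*. Decisions
taken where the source states only "significant":

* **Directionality.** By default inclusion also requires the case mean to
  exceed the control mean, so codes *suppressed* after diagnosis are not
  admitted as cancer-related; the pure two-sided rule is a switch.
* **Degenerate samples.** If both samples are constant the statistic is
  undefined; we set \(p = 1\) when the means are equal and \(p = 0\) when
  they differ, preserving the intuitive decision. Samples with fewer than
  two observations yield an "insufficient data" exclusion with a logged
  reason.
* **No multiplicity correction** (the source uses raw \(p < 0.05\)); the
  audit table carries all p-values so corrections can be applied downstream.

Concordance between D-list and C-list is the ratio of codes in both to codes
in the D-list, weighted by each code's number of occurrences — by default
counted over the case windows of the self-control subcohort, keeping the
metric inside the validation sample (whole-cohort weights are a switch).
D-list codes never administered carry zero weight: the data can neither
confirm nor contradict them.

## The synthetic generator

No deposited dataset accompanies the reference study, so the package
generates linked synthetic data with the statistical structure the analysis
assumes. Diagnosis dates are uniform over an 8-year accrual window
(2003-01-01 to 2010-12-31); survival after the prevalence date is
exponential with hazard 0.06/yr, giving roughly 5% cancer deaths in the
follow-up year as in the reference cohort, with 15% of deaths from
non-cancer causes (producing censored patients). Per code, events follow a
piecewise-constant Poisson process: background rate \(\lambda_0\) before
diagnosis and \(\lambda_0 + \lambda_{\text{period}}\) after, where the
excess follows the phase periods (first year after diagnosis; last year of
life, taking precedence where the two overlap; the time between). Finer
temporal structure would be unidentifiable through 12-month windows and is
deliberately omitted. The demo profile (n = 500) plants 10 cancer-related
codes with excesses of 0.8–3.0 events/patient-year over backgrounds of
0–1.0, alongside 20 background-only null codes and never-listed distractor
codes; hospital events are packaged into multi-slot episodes with distractor
codes in the unrelated slots so the at-least-one-code rule is exercised
non-trivially.

What the generator does *not* emulate: regional coding dialects, DRG
tariffs, morphology- or stage-specific trajectories, seasonality, and
correlation between codes beyond co-occurrence on hospital episodes. Passing
tests therefore demonstrate that the pipeline recovers planted structure
under the stated stochastic model, not that the demo D-list is clinically
complete. One realistic artefact is worth knowing about: distractor codes
riding along on cancer admissions become genuinely elevated post-diagnosis,
so the self-control test may legitimately include some of them — the
analogue of generic codes (ECGs, X-rays) entering empirical lists in real
data.

## Problem sizes and runtime choices

The default validation runs use n = 500 patients (yielding a self-control
subcohort of roughly 60), 2000 replicated null subcohorts of 50 patients for
the type-I-error check, and 1000 random vectors for the t-test agreement
check (tolerance 1e-8 against the reference implementation). These sizes
give Monte-Carlo error well inside the asserted bounds (99% binomial
interval around 0.05 for the null inclusion rate) while keeping a full test
run under a minute.

## Known limitations

* The counts are paired self-controls but are tested, as in the source
  design, with an independent-samples test; a paired or count-model
  (Poisson/negative-binomial) variant is out of scope.
* The cross-sectional design assigns each patient one phase on the
  prevalence date; longitudinal decomposition, where one patient contributes
  person-time to several phases, is a non-goal.
* The bundled D-list is a reduced illustrative list spanning every category
  and sub-category, not the full clinician-validated 202/250/60-code lists.
* Cost estimation (tariff valuation of attributed events) is outside the
  package's scope.
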
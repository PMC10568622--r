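---
title: "Trigger-tool methods: screening rules, adjudication scoring and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trigger-tool methods: screening rules, adjudication scoring and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gttade)
```

## The screening model

A *trigger* is a screening rule over an admission's tabular record. Every
rule in the 36-item registry has up to three parts, and a hit requires all
of them:

1. **The condition** — a laboratory threshold (L-rules), the administration
   of a rescue/antidote drug (T-rules), a clinical event code (C-rules), or
   an abruptly stopped order (I1). Comparison operators are taken literally
   from the rule definitions: `<` and `>` are strict, `≥`/`≤` inclusive, so
   K⁺ = 3.0 mmol/L does *not* fire L1 (K⁺ < 3.0) while TSH = 5.0 mIU/L
   *does* fire L10 (TSH ≥ 5.0).
2. **The drug context** — where the rule names a causative class
   ("hypokalaemic drugs used"), a drug of that class must be *active*
   within a window before the observation: its half-open administration
   interval `[start, stop)` must overlap `[t − w, t]`. The window `w`
   defaults to 7 days (`gtt_config(drug_window_days = )`). The rules
   themselves state no window; most ADEs in this population arise within
   two days of administration, so seven days is a deliberately generous
   envelope that changes little in practice. Rules whose definition names
   no drug class (e.g. L6 liver injury, L8 coagulation, C1 rash) impose no
   drug-context requirement.
3. **Exclusion clauses** — positive-evidence comorbidity flags (no L15 hit
   in documented gout/hyperuricaemia; no L10 hit in known thyroid
   dysfunction; no L6 hit on parenteral nutrition or with hepatobiliary
   disease). A missing context row means *all flags false*, i.e. exclusion
   requires explicit evidence.

**Counting policy.** The default counts at most one hit per admission and
trigger per stay (the earliest qualifying observation), which is the
conservative chart-review reading; `counting_policy = "per_occurrence"`
keeps repeats. The development study's positive-trigger total does not
state how repeat firings were counted, so the policy is explicit and
configurable rather than hidden.

### Rule-specific interpretation choices

Some definitions leave room that had to be closed:

* **L5 (hyperglycaemia), diabetic branch.** "Glucose higher than in the
  past" has no defined baseline. Implemented as: any glucose value
  exceeding the admission-period minimum by a configurable margin
  (`diabetic_rise_margin`, default 3.0 mmol/L — roughly the gap between the
  non-diabetic fasting and postprandial cut-offs). This is flagged as an
  interpretation, not a published threshold.
* **L6 / L12 ULNs.** The liver-enzyme rule is stated relative to the upper
  limit of normal without printing ULNs; these are site-specific registry
  parameters (defaults ALT 40 U/L, ALP 150 U/L, CK 200 U/L).
* **L7 (kidney injury) baseline.** The baseline creatinine is the lower of
  the admission value (accepted from a 48-h pre-admission lookback) and the
  in-stay minimum — equivalently the series minimum. The oliguria clause
  (urine output < 0.5 mL/(kg·h) sustained > 12 h) is evaluated only when a
  urine-output series exists.
* **L8 (coagulation).** PT > 12.1 s, APTT > 36.5 s, INR > 3.5 are
  hospital-adjusted values and therefore config defaults, not constants.
* **L12 (myopathy).** The published compound criteria mix muscle evidence
  (CK > 10 × ULN, myalgia/myositis) with a creatinine-rise criterion that,
  taken alone, is indistinguishable from L7. The predicate therefore
  requires muscle evidence — CK above 10 × ULN or a myopathy-type clinical
  event — in a patient without primary muscle disease; the creatinine rise
  is treated as supportive, not sufficient.
* **I1 (abrupt stop).** Fires on the `abrupt_stop` flag of any order. The
  proposed extension to dose *reductions* is available as
  `gtt_config(i1_include_dose_reduction = TRUE)` but off by default, to
  keep the primary validated list intact.

Units are fixed per analyte and validated at load; the engine never
converts units, because every threshold is stated in exactly one unit.

## Adjudication scoring

Causality review is human work; the package represents it as data and
implements only the instruments. The Naranjo questionnaire weights
(+1/0/0, +2/−1/0, +1/0/0, +2/−1/0, −1/+2/0, −1/+1/0, and +1/0/0 for items
7–10) ship as `inst/extdata/naranjo_items.csv` so the scoring table is
auditable; categories are definite (≥ 9), probable (5–8), possible (1–4),
doubtful (≤ 0), and only definite/probable ADEs enter the analyses.
Severity descriptors map bijectively to CTCAE grades 1–5. Onset times are
binned on half-open intervals (lower, upper] — at most 5 h, 5 h–1 day,
1–2 days, 2–4 days, 4–8 days — with onsets before admission binned
`prior_to_admission`; an onset after admission but before the suspect
drug's first administration is rejected as inconsistent.

An ADE may be linked to several trigger hits. Detection *pairs* count each
link, so the PPV numerator (pairs) can exceed the number of detected ADEs;
detected + undetected always equals the ADE total.

## Metrics and numerical conventions

All rates are computed in full precision and rounded only at rendering,
with base R's round-half-to-even at two decimals. This convention
reproduces the conventional presentation of every rate the package reports,
including the occurrence-rate boundary case 51/480 = 10.625% → 10.62 (a
round-half-up rule would print 10.63). The sample-size formula
N = Z²P(1−P)/δ² rounds to the *nearest* integer (384.16 → 384), not the
ceiling, and refuses δ below 10⁻⁶.

Patient-days are the sum of lengths of stay; when reproducing the
summary-level panel the fixture uses 480 × 8.95 = 4,296 patient-days. The
monthly series attributes an admission's full stay to its admission month,
and months with no admissions are reported as missing, not zero.

Two published inconsistencies are carried as-is rather than resolved:

* The organ-system table totals 61 symptom entries over 56 ADEs, but its
  metabolic/nutritional row prints count 8 beside a percentage that implies
  15 (and sub-counts summing to 7). The counts fixture reconciles that row
  to 15 so the entries sum to the printed total of 61 and every printed
  percentage (e.g. gastro-intestinal 17/61 = 27.87%) is derivable from
  counts; the two published values for the metabolic share (24.53 and
  24.59%) are both noted here and neither is "chosen".
* "ADEs within 2 days" can be read cumulatively two ways: the onset table's
  first three bins give 42/56 = 75.00%, while 40/56 = 71.43% corresponds to
  a strictly-within-2-days reading. `distribution_tables()` returns the
  bins; both cumulative conventions can be computed from them.

## The logistic risk model

`fit_logistic()` is a maximum-likelihood logistic regression via
iteratively reweighted least squares: convergence when the log-likelihood
changes by < 10⁻⁸, at most 50 iterations, Wald standard errors from the
observed information, 95% CIs as exp(β ± 1.96 SE). Quasi-separation
(coefficient drift or saturated fitted probabilities) is flagged and the
fit marked non-converged rather than silently reported. The covariate set
mirrors the development study's model — length of stay, number of
diagnoses, number of medications, antibacterial use and its duration,
entered simultaneously; age and sex appear only in the group comparisons,
and that omission is deliberate, reproducing the published model. Group
comparisons use the two-sample rank-sum test for continuous covariates and
the chi-square test without Yates continuity correction by default (the
published analysis does not state the variant; a toggle exists). Analyses
are complete-case.

The published regression coefficients themselves are not reproducible
without the original patient records; they are covered instead by
parameter-recovery properties — simulated cohorts with a true
per-medication log-OR of 0.087 must be recovered without bias as n grows,
which the test suite checks at n = 500–8,000 and the acceptance script at
n = 2,000.

## The synthetic cohort generator

`generate_cohort()` exists so that every pipeline stage is testable with
known ground truth. What it emulates:

* **Marginals** of the development cohort: age, stay length, medication
  and diagnosis counts as truncated normals (age 72.61 ± 5.94 on [65, 91],
  stay 8.95 ± 4.57 days on [2, 27], medications 18.26 ± 6.42 on [5, 40],
  diagnoses 5.38 ± 2.80 on [1, 19]); sex (45.62% female), allergy history
  (14.38%), antibacterial use (30.83%) with a lognormal duration matched to
  53.42 ± 103.24 h on [3, 528] (a truncated normal cannot hold a mean below
  its SD on that support). Truncated-normal parameters are
  *moment-calibrated*: the generator solves for the underlying normal so
  the truncated distribution itself has the stated mean and SD — naive
  truncation at 65 of a Normal(72.61, 5.94) would inflate the mean by about
  one year.
* **Planted trigger conditions** per rule, at per-admission rates
  proportional to the development cohort's positive counts. Each plant
  inserts exactly the rows its predicate needs — the abnormal value, the
  context drug started shortly before it, the event — and forces the
  relevant exclusion flags off (or on, where the rule requires one).
  Background laboratory values are drawn from ranges that cannot cross any
  registry threshold, and background medications never include the antidote
  names, so on a noise-free cohort the engine's hit set equals the plant
  list exactly. A `noise_rate` plants additional spurious conditions,
  recorded in the ground truth as noise. Every planted condition is
  re-evaluated by the engine at generation time (`verify = TRUE`).
* **ADEs** via a logistic model in the medication count with the published
  per-medication log-OR 0.087; the intercept is solved numerically against
  the medication-count marginal so the expected ADE-patient fraction equals
  10.62%. ADE multiplicity (47:3:1 patients with 1:2:3 events), onset-bin,
  organ-system and severity distributions follow the published tables, and
  ADEs are linked to planted triggers with a detection probability of
  52/56. Naranjo answer sets are generated to land in the intended
  category, plus a stream of possible/doubtful candidates that exercise the
  causality filter.

What it does **not** emulate, and what passing tests therefore do not show:
no pharmacokinetics, no correlation structure between marginals (the
development study publishes none, so independence is assumed and stated),
no seasonal admission pattern beyond uniform months, no free-text evidence,
and background labs deliberately avoid borderline values — so the tests
demonstrate rule correctness and pipeline calibration, not performance on
the messier distributions of real hospital data.

Timestamps are ISO-8601 at minute resolution (UTC) throughout; identical
seeds give byte-identical CSV output.

## Problem sizes used in the checks

The package's own test suite exercises generated cohorts of 10–480
admissions (the full study size for recall and calibration checks, 20-
admission cohorts for brute-force oracle equivalence over all 36 rules, 50
seeds for marginal calibration) and logistic fits up to n = 8,000; these
sizes make the whole suite run in a few minutes on one CPU while keeping
every Monte-Carlo band at 3 standard errors or wider.

## Known limitations

* The trigger list targets non-oncology inpatients aged ≥ 65; the
  exclusion flags (malignant tumour, transplant, palliative care, ICU
  transfer) are eligibility filters, not risk adjustments.
* T-rules match administrations by drug name against a configurable
  formulary; a deployment must map its own formulary into the registry.
* The engine detects *trigger conditions*; it never asserts causality.
  PPV and ADE rates require reviewer adjudications as input.
* Reported p-values are unadjusted, matching the published analysis; no
  variable selection or penalization is performed.
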
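---
title: "Methods: triage rules, instrument scoring, and the pilot analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triage rules, instrument scoring, and the pilot analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfcompanion)
```

hfcompanion implements the computational core of a mobile self-care program
for adults with chronic heart failure (HF). Fluid retention in decompensating
HF shows up as rapid weight gain, which makes daily weight the key
telemonitoring signal; the package combines that signal with a four-level
symptom report to place each patient-day in an escalating triage zone, scores
the patient-reported-outcome battery used around such programs, quantifies
app engagement from access logs, and analyses a small two-arm pilot trial of
the program. This vignette explains the models and rules, the defaults and
why they are set where they are, and what the synthetic-data generators do
and do not emulate.

## The zone triage model

Each day the patient reports a weight and a symptom level (`stable`, `mild`,
`moderate`, `immediate`). Two weight-gain features are derived:

* `delta_1d` — today's weight minus the most recent prior weight. If that
  weight is older than one day it is carried forward for up to 3 days
  (`staleness_days`, configurable); beyond that the delta is treated as
  missing and only symptom rules apply. Daily weighing gaps are common in
  home monitoring, and a short carry-forward keeps the one-day rule usable
  without inventing data.
* `delta_7d` — today's weight minus the *minimum* weight in the half-open
  trailing window `(today - 7 days, today)`. A gain "over the week" is
  measured against the week's low point because that is the most sensitive
  (fail-safe) reference; a mean or first-of-window reference would mask a
  dip-then-rise pattern that is exactly the fluid-retention signature of
  interest.

The zone rules, evaluated most-severe-first with the most severe fired rule
deciding the zone:

| zone | condition | action |
|------|-----------|--------|
| red | symptoms require immediate attention | emergency record (911 placeholder, panic alert to coordinator and home care) |
| orange | moderate symptoms **and** gain > 5 lb | call the provider now; coordinator notified |
| yellow | mild-or-worse symptoms, **or** gain ≥ 3 lb in 1 day, **or** ≥ 5 lb in a week | self-action: extra diuretic dose if prescribed, call home care |
| green | no rule fired | continue current self-care practices |

Three deliberate choices deserve a note:

* **Precedence.** The zones are worded as escalating conditions without an
  explicit precedence, so the engine evaluates red → orange → yellow → green
  and takes the most severe match. Most-severe-first is the fail-safe
  resolution when conditions overlap (e.g. moderate symptoms with a 6 lb
  gain also satisfies the yellow weight rules).
* **Moderate symptoms without a large gain map to yellow, not green.** Read
  literally, the yellow wording names only mild symptoms; but a rule set in
  which *moderate* symptoms with no weight change landed below *mild*
  symptoms would be non-monotone in severity, which no clinician would
  accept from a triage tool. The engine therefore lets the yellow symptom
  rule fire for mild *or* moderate, preserving monotonicity: the zone never
  decreases as severity rises at fixed deltas, or as either delta rises at
  fixed severity. The test-suite checks this property explicitly.
* **Boundaries.** Yellow thresholds are inclusive (≥ 3 lb, ≥ 5 lb); orange
  requires *strictly more than* 5 lb, following the "more than 5 pounds"
  wording. A 5.0 lb weekly gain with moderate symptoms is yellow, not
  orange. "No change in weight" for green is implemented as "no weight rule
  fired", so sub-threshold fluctuations (including losses) stay green when
  symptoms are stable.

All thresholds live in the configuration (`hf_config()`), in pounds; weights
arriving in kilograms are converted at 2.20462 lb/kg on ingestion. One
assessment per patient-day is kept, last-write-wins. Every action the engine
emits is an inert record with `dry_run = TRUE`; the package never performs
notification, telephony, or network side effects.

The NYHA severity index is a configurable rule ladder (symptoms at rest →
IV; with less-than-ordinary activity → III; with ordinary activity → II;
otherwise I). The mapping ships as data rather than code because programs
differ in how they phrase the probe questions. Similarly, when symptoms are
collected per-item the overall level is the *maximum* item level — one
alarming answer escalates the day.

## Instrument scoring

The scorers implement the battery's published structure: PHQ-9 (9 items
0–3, total 0–27, cutpoints 5/10/15/20, probable-major-depression flag at
≥ 10, higher is worse), AHFKT knowledge test (30 keyed items, 0–30, higher
is better), MMAS-8 adherence (7 binary items plus a 5-level frequency item
mapped to 0/0.25/0.5/0.75/1; total 0–8 non-adherence points, *lower* is
better), FSSQ social support (8 items 1–5), CIRS illness burden (14 organ
systems 0–4, total 0–56), SCHFI self-care subscales, and KCCQ.

Two scoring conventions were genuinely open and are resolved as follows:

* **SCHFI is scored as raw item sums by default** (maintenance 10 items,
  management 6, confidence 6, each 1–4). The pilot reports subscale scores
  with magnitudes near 23 (maintenance) and 12–21 (management), which sit on
  the raw-sum scale, not the standardized 0–100 scale; a
  `standardize = TRUE` switch provides the 0–100 rescaling for
  interoperability. Item counts per subscale are configuration because SCHFI
  versions differ.
* **KCCQ uses the conventional domain algorithm**: each of the five domains
  (physical limitation, symptoms, quality of life, social interference,
  self-efficacy; item membership in config) is the mean of its answered
  items rescaled to 0–100, computed when at least half the domain's items
  are answered; the overall summary averages the four clinical domains,
  excluding self-efficacy, the conventional choice. The study reports the
  instrument's item and domain counts but not its scoring arithmetic, so the
  conventional algorithm is used and is config-overridable.

The eligibility gate evaluates *all* criteria rather than short-circuiting,
so screening reports list every violated criterion: inclusion requires a
recent HF hospitalization, NYHA II–III, age ≥ 30, English, corrected near
vision 20/50 or better, a passed hearing screen, and willingness to use the
app; exclusions are transplant status 1A or home inotropes,
palliative/hospice care, stroke in the past year, aphasia or major
disability, uncontrolled psychiatric disorder, MoCA < 20, and dependent
living. The hearing criterion is a pass/fail boolean supplied by the
screener: the published threshold wording for the audiometric screen is
internally inconsistent (decibel values far outside the HL scale), so the
package does not attempt audiometric computation.

## Engagement analytics

Engagement is `100 × distinct active days / protocol window length`, with a
30-day window by default — so 24 active days is 80%. The denominator is the
protocol window, not days-until-last-use: an early dropout genuinely has low
engagement. Day attribution uses the patient-local date written in the
timestamp itself (the ISO-8601 date part under the event's own zone
offset), so a patient's 11 pm session counts for that patient's day
regardless of server time zone. Within-day duplicates collapse; event order
is irrelevant. The low-engagement flag defaults to < 50% active days — the
program's monitoring protocol implies daily dashboard review but states no
cutoff, and half the protocol days is a conservative screening line for a
coordinator's attention. The cohort engagement number is the unweighted mean
of per-patient percentages.

## Exercise feedback

Breathing sessions are scored against the paced-breathing target of 6
breaths/min (versus spontaneous breathing near 15/min): the session rate is
60 over the mean inter-breath interval, and the score is the percentage of
intervals whose instantaneous rate falls within ±1 breath/min of target.
The ±1 band is a package default — the program names the target but no
tolerance — chosen tight enough that spontaneous breathing scores 0.

Walking feedback compares the distance walked with a personalized
expectation from a published healthy-adult six-minute-walk reference
regression on age, sex, height, and weight (the Enright–Sherrill equations;
sex-specific linear coefficients in a pluggable registry). The program
computes its expectation from the same four inputs but its own formula is
unpublished, so the package ships the published reference as default and
documents that substitution. The score is `100 × distance / expected`,
capped at 100; over-achievement is neither penalized nor rewarded, because
the feedback's purpose is encouragement toward the 3–4 sessions/week goal,
not a fitness ranking.

## The pilot analysis

Outcomes are analysed as change scores (30-day minus baseline) over
completers only, with no imputation — matching a pilot in which 13 of 18
randomized participants (7 intervention, 6 control) completed follow-up.
Between-arm comparisons use **Student's pooled-variance t** with
`df = n1 + n2 − 2`; the pooled form (rather than Welch) is forced by the
printed df of 11 for arms of 7 and 6. Effect sizes are **partial eta
squared** from the regression of change on a group indicator,
`SS_effect / (SS_effect + SS_error)`; for two groups this is algebraically
`t² / (t² + df)`, and the test-suite verifies the two computational routes
agree to 1e-10 across 1000 random datasets. Degenerate inputs are pinned:
identical data give η² = 0, zero residual variance with differing means
gives η² = 1, and a zero-variance t-test returns t = 0 when means agree.
P-values are two-sided and unadjusted — the pilot applies no
multiple-testing correction, and neither does the package.

Sample-size projection converts η² to Cohen's f = √(η²/(1−η²)), doubles it
to the two-group standardized difference d = 2f, and applies the
normal-approximation formula `n = 2((z₁₋α/2 + z_power)/d)²` per arm with
α = 0.05 and power 0.80 by default, rounded up. The z formula undershoots
the exact noncentral-t computation by a subject or two at pilot-sized
effects; the tests bound that gap against `stats::power.t.test`.

The pilot's own printed effect sizes cannot be recomputed from published
group summaries (they require the individual change scores), so the package
validates the *method* — the algebraic identity above plus parameter
recovery on simulated cohorts — rather than asserting those printed values.
Where the pilot's abstract and its results table disagree arithmetically
(the control quality-of-life change), the table endpoints are treated as
canonical.

## What the synthetic cohorts emulate

`simulate_patient_history()` emulates the *threshold-crossing structure* of
telemonitored weight: a Gaussian random walk (default step SD 0.6 lb, a
typical day-to-day scale fluctuation) around a 180 lb baseline, with
fluid-retention episodes that begin with probability 0.05/day and add
1.5 lb/day for 4 days — enough to cross the 5 lb/week rule, as a real
decompensation would. Symptom severity is linked to the trailing 7-day gain
(mild at 3 lb, moderate at 5, immediate at 10), and app access is Bernoulli
per day at 0.8 — the neighborhood of the program's observed "24 of 30 days"
usage. It does not emulate diurnal weighing variation, scale measurement
error, symptom reporting that disagrees with weight, or hardware-driven
disengagement; passing tests therefore demonstrate correct rule arithmetic
and pipeline behavior, not clinical performance on real patients.

`simulate_outcome_table()` draws each participant's (baseline, follow-up)
pair per outcome from a bivariate normal with the configured marginal means
and SDs — defaulting to the pilot's printed group summaries
(`study_outcome_params()`) — and a within-patient correlation of 0.5. The
pilot reports only marginal SDs; 0.5 is a mid-range test-retest correlation
for these instruments and gives change-score SDs of realistic size.
Attrition is completely at random (default rate 5/18, the pilot's), or
fixed per-arm completer counts for analyses that need the 7-vs-6 layout;
the completely-at-random mechanism is an assumption, not an observed fact.
Allocation follows the pilot's alternating 3:3 / 2:2 blocks; a final
partial block is drawn balanced so that 18 participants always land 9 per
arm, and prefix imbalance never exceeds half the largest block.

Generators consume an integer seed and are bit-reproducible; the pipeline
writes byte-identical artifacts on repeated runs over the same inputs.

## Problem sizes and numerical notes

The test-suite exercises the zone classifier on the full
9 × 11 × 4 delta-severity lattice against an independent rule-enumeration
oracle; the effect-size identity on 1000 random datasets; parameter
recovery on 500 simulated 7-vs-6 cohorts (bias within 3 Monte-Carlo SEs of
the configured truth per outcome); and the eligibility gate against a
brute-force conjunction over all 1024 combinations of its ten boolean
criteria. These sizes make the whole suite run in well under a minute on a
single CPU while keeping Monte-Carlo standard errors small relative to the
tolerances tested. Ties and boundaries are resolved as stated above
(inclusive yellow thresholds, strict orange threshold, last-write-wins
within a day); all scorers validate item counts and ranges before any
arithmetic and report the first offending item index.

## Limitations

The package is the computational core only: no UI, no notification
delivery, no device ingestion (vitals arrive as plain columns). The symptom
questionnaire items and their mapping to the four severity levels are
program-configurable because the source program does not publish them; the
default rubric (maximum item level wins) is documented but not asserted to
be the program's. The walking expectation uses a published population
reference, not the program's own formula. And the pilot-analysis module
reproduces a *method* appropriate to an 18-participant feasibility study —
its outputs on such small samples are effect-size estimates for planning,
not confirmatory evidence.
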
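---
title: "Cohort identification with attrition provenance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort identification with attrition provenance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortforge)
```

## The problem

Hospital-wide longitudinal records — diagnoses, dispensings, procedures,
encounters, demographics — can answer surveillance questions ("how many of
our fracture patients ever receive secondary prevention?") far faster than
a purpose-built registry, provided the cohort logic is explicit, auditable
and reusable. cohortforge models that workflow as data: reusable code-set
*templates*, declarative *identification specs*, a hierarchical *patient
mart* with per-step attrition, and a *report service* of three summary
views. This vignette records the modelling assumptions, the numerical
conventions, and the design decisions that were genuinely open.

## Data model

Three tables keyed by an opaque `patient_id`: patients (birth date, sex,
BMI in kg/m², marital status, income level, occupation, death date),
clinical events (date, dimension, code, care setting, and — for pharmacy
rows only — the days a dispensing covers), and encounters (date, setting).
Unknown categorical values are the literal `"unknown"`, never an empty
string, so missingness is distinguishable from malformed input. Exact
duplicate event rows are dropped at construction with a logged count:
claims extracts commonly repeat lines, and all cohort logic is set-based,
so duplicates carry no information here. Serialization is headered CSV with
ISO-8601 dates in canonical row order; write-then-load is the identity and
two writes are byte-identical, which keeps fixtures diff-able.

Laboratory events are modelled with code and date only — enough for
criterion matching; result values are out of scope.

## Code matching

ICD-9 codes are stored dotted (`820.21`); the 3-character category is the
matching unit:

* `prefix "820"` matches the bare category or any dotted subcode, never a
  code whose category merely shares digits (`8200` does not match). Real
  records carry 4–5 digit codes while study definitions cite 3-digit
  categories; dotted-prefix semantics make the correspondence unambiguous.
* `range 140–208` is inclusive at both ends on the integer value of the
  leading 3 characters; V and E codes never match a numeric range.
* Pharmacy codes are matched exactly against canonical lowercase drug
  names, since drug lists in study definitions are given by name. The
  built-in `aom` template carries the nine anti-osteoporosis agents
  (alendronate, zolendronate, ibandronate, denosumab, raloxifene,
  teriparatide, estradiol valerate, conjugated estrogens, calcitonin).

A property test checks every built-in template against an independent
regex oracle on 10^4 random ICD-9-shaped strings.

## Windows, index rules, attrition

All criterion windows are inclusive day-offset intervals relative to the
member's index date. Published cohort definitions state windows in
calendar language ("within 1 year before"); day offsets are the
unambiguous rendering and match new-user-design practice:
lookback "within 1 year before" is `[-365, -1]`, follow-up "within
3 months" is `[+1, +90]`, treatment "within 1 year after" is `[+1, +365]`.
The index day itself belongs to neither side — a dispensing on the index
date neither disqualifies a new user nor counts as post-index treatment.
The 1-year lookback is applied uniformly to all four exclusions of the
packaged study (malignancy, prior fracture, Paget disease, prior AOM);
the source material is explicit about it only for some of them, and
uniformity is the conservative, testable reading.

Ages are completed years by birthday-anniversary arithmetic (a 29 February
birthday increments on 1 March off-years), property-tested against a
year-walking oracle.

**Index rule.** The index date is the earliest in-window matching
diagnosis; several qualifying codes on that day collapse to one index
(set semantics). The rule's `first_ever` flag decides how pre-window
history is handled, and this was the one genuinely open design point.
"Newly diagnosed" admits two readings: (a) no matching diagnosis ever
before the observation window, enforced at the index stage; (b) first
in-window occurrence, with incident-user screening left to an explicit
1-year lookback exclusion. The two are not interchangeable for
provenance: under (a) a patient with recent prior disease silently never
indexes, so a named "no prior fracture" step can never remove anyone —
any matching event in `[-365, -1]` that is on/after the window start would
itself have been the index, and any event before the window start already
blocked indexing. The engine therefore implements both: `first_ever =
TRUE` is the default and the stricter washout, while the packaged fracture
study sets `first_ever = FALSE` and carries the explicit lookback
exclusion, so that prior-fracture attrition is attributed to its named
step, as clinical study flowcharts report it.

**Attrition.** Criteria run in declared order; a patient removable by
several criteria is counted only under the first (sequential attribution).
Consequently the *final member set* is invariant under permutation of
exclude-criteria order — only the per-step counts move — which is
property-tested, and every record satisfies
`index − Σ excluded = remaining` (asserted on every run). Patient lists
chain: a spec may name an earlier list (by case number or topic) as its
candidate source, members are always a subset of the parent's, and the
attrition report concatenates records root-to-leaf.

Case numbers are version-4 UUIDs; determinism is promised for member sets
and attrition, never for identifiers or timestamps.

## Report service

*Characteristics*: mean, sample SD (n−1 denominator, cross-checked against
a two-pass computation at 10⁻¹⁰ relative tolerance) and non-missing count
for age-at-index and BMI; per-level counts and percents over n for sex,
marital status, income level, occupation. *Trend*: calendar-aligned
monthly/quarterly/yearly buckets spanning the list's observation window
(quarters are Jan–Mar … Oct–Dec, labelled "YYYY Qn"); bucketing is a
partition, so totals are conserved under any stratification. Stratification
by `fracture_type` classifies each member hip / vertebral / both from which
fracture templates the index-day codes matched — multi-code index days are
real and need an explicit rule. *Proportion trends* divide per-bucket
counts of a nested list by its parent; empty-denominator buckets report
`NA` rather than 0. Percent strings round half-up at caller-chosen 0–2
decimals, because published tables mix integer, 1-dp and 2-dp displays;
rounding is a report parameter, not a constant.

Reports are plain tibbles/CSV; charting is presentation-layer and out of
scope.

## Pharmacy duration correction

Long-acting injectables (annual zolendronate, six-monthly denosumab,
quarterly ibandronate) are commonly recorded as 1-day prescriptions.
`normalize_durations()` is an opt-in correction: where the recorded
duration is exactly 1 day and the drug's canonical duration exceeds 30
days, the canonical value is substituted; everything else is untouched.
The packaged study does not depend on it (its criteria use dispensing
*dates*), but exposure-duration analyses would.

## What the generators emulate — and what they do not

**Fixture mode** constructs mutually exclusive patient categories, each
violating exactly one step of the packaged study (or none): eligible
treated/untreated, no-follow-up, prior malignancy / fracture / AOM / Paget
history, under-50, and outside-window. Mutual exclusivity makes sequential
attribution unambiguous, so engine-computed attrition equals the
construction *exactly* — which is what the fixture is for: it turns the
whole pipeline into a checkable identity. Index dates go round-robin over
the window's calendar quarters; `prior_fracture` patients are confined to
the first two quarters, with the prior event 180 days before the index, so
the prior event predates the window start (anywhere later it would itself
become the index). Demographics are drawn once per patient from fixed,
realistic distributions (age ~ N(76, 10) truncated to 52–95 years, 75%
female, BMI ~ N(23, 3.9) with 5% missing, 99% normal income) — chosen to
sit in the regime of an elderly fracture population and not revisited.

**Population mode** draws independent patients: age anchored at the
observation start; a yearly first-fracture incidence (default 0.05/year);
given a fracture, independent Bernoulli treatment (`p_treat`, default
0.21, dispensing uniform in days 1–365) and follow-up (`p_fu`, default
0.82, encounter uniform in days 1–90); background lookback comorbidity at
small rates; plus one noise encounter and one non-fracture diagnosis per
patient. Because exclusions are independent of the treatment and follow-up
draws, the engine's estimated proportions are unbiased for `p_treat` and
`p_fu` up to two small, bounded contaminations: a background *in-window*
prior fracture shifts the index earlier (diluting both estimates by
roughly `p_prior_fracture` × the affected fraction, well under one
percentage point at defaults), and the noise encounter can fall in the
follow-up window (inflating follow-up by ≈ 90/1826 of the non-followed
share). Both are far inside the 3-binomial-SE bands the tests assert.

Neither mode models disease progression, re-fracture, coding noise,
mortality censoring, or seasonality. Passing tests therefore demonstrate
that the *engine logic* is exact and that parameters are recovered under
the generator's assumptions — not that the packaged study would reproduce
any particular hospital's absolute counts, which depend on real coding and
visit behaviour.

## Numerical and degenerate-input choices

* Empty index sets are valid empty lists with attrition recorded, not
  errors; empty datasets flow through every view (characteristics reports
  n = 0).
* Validation returns violations as data (table, row key, rule id), one row
  per violation; only structurally fatal problems — missing files,
  unparseable dates, dangling patient references — abort a load.
* Half-up decimal rounding uses a √ε guard against binary representation
  of exact halves.
* Generators isolate their RNG behind the spec's seed and restore the
  caller's stream, so identification runs interleave with seeded
  simulations without breaking reproducibility.

## Problem sizes

The test suite exercises: the full flowchart fixture at its full
scale (≈4700 patients, sub-second), 100 random datasets of 50–500 patients
against a naive per-patient interpreter that shares no code with the
engine, 25 random fixture specs, and a 5000-patient population for
parameter recovery — sizes chosen to make every property decisive while
keeping the suite fast enough to run on every change.

## Known limitations

ICD-10 and ATC-hierarchy traversal are not implemented (exact/prefix/range
on ICD-9 and exact drug names only). The mart is in-memory with a flat-file
persistence format; there is no concurrency, access control, or incremental
refresh. Laboratory events carry no result values. The income taxonomy is
an opaque two-level categorical.
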
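---
title: "Criteria-based FHIR preprocessing: model, semantics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Criteria-based FHIR preprocessing: model, semantics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(fhirprep)
library(dplyr)
```

## The problem

Electronic health records exported as HL7 FHIR resources are convenient for
exchange but awkward for statistics: each record is a nested JSON document,
values of interest sit several levels deep, and the clinically meaningful
questions ("hemoglobin results of men aged 18–65 with no malignancy on
record and no surgery within 90 days") span several resource types linked by
references. Before any model can be fitted, such data must be flattened into
a per-row table, with rows admitted or removed by criteria that look across
resources and across time.

`fhirprep` implements that preprocessing step as a small, testable pipeline:

1. a **document store** holding minimally parsed resources in a single
   table (`id`, `fhir_id`, `type`, raw JSON `data`, plus extracted index
   columns),
2. a JSON **filter-specification language** expressing a base resource
   selection and conjunctive inclusion/exclusion criteria,
3. a **filter engine** with explicit temporal semantics,
4. a **feature builder** producing flat, analysis-ready tables, and
5. a **synthetic hospital data generator** with ground-truth labels, so the
   whole pipeline can be validated offline.

The package deliberately stops where dedicated tools start: it does not fit
reference-interval mixture models, it is not a FHIR server, and it supports
no temporal logic beyond day-windows and encounter periods (no "first
observation after X" operators, no nested boolean structure across
criteria).

## The resource model

Six resource types are parsed: Patient, Encounter, Condition, Procedure,
Observation and MedicationStatement. Parsing is index-oriented: the raw
document is retained verbatim (so stores round-trip byte-for-byte), and only
the fields the engine needs are lifted out — patient and encounter
references, codings, a numeric value with unit, demographics, and one
**anchor time** per resource:

| type                | anchor time                        | fallback                  |
|---------------------|------------------------------------|---------------------------|
| Observation         | `effectiveDateTime`                | `issued`                  |
| Condition           | `recordedDate`                     | `onsetDateTime`           |
| Procedure           | `performedDateTime`                | `performedPeriod.start`   |
| MedicationStatement | `effectiveDateTime`                | `effectivePeriod.start`   |
| Encounter           | `period.start` (period kept whole) | —                         |
| Patient             | none (timeless)                    | —                         |

Reducing every non-Encounter resource to a point time is a deliberate
simplification: the matching logic reasons about point times for base and
criterion resources, and the Encounter is the only range-bearing type it
consults. Which timestamp element best represents a laboratory result varies
between installations; the `effectiveDateTime`-first rule is this package's
choice and is confined to one function (`resource_time()`).

All timestamps are reduced to seconds since the Unix epoch in UTC.
Date-only strings ("2017-03-02") are read as midnight UTC, which keeps
interval arithmetic deterministic regardless of session timezone or locale.
Ages are completed years at a given instant, with a February-29 birthday
completing on March 1 in non-leap years.

## Filter semantics

A specification names a **base selection** — a resource type, a code
selector, and optional value, demographic, and calendar restrictions — and a
list of **criteria**. Criteria combine as a conjunction: a base resource is
kept exactly when every inclusion criterion matches it and no exclusion
criterion does. Disjunction exists only inside a code list.

A criterion is grounded in resources of another type matching its own code
selector (and optional value filter). It matches a base resource `b` of
patient `p`:

* **ever mode** — when any grounding resource of `p` exists, at any time.
  Ever-mode criteria act at patient level and are evaluated once per
  patient.
* **window mode** — when some grounding resource `c` of `p` satisfies
  either
  * (a) `time(b) ∈ [time(c) − w_before·86400 s, time(c) + w_after·86400 s]`, or
  * (b) `time(b)` lies inside the period of `c`'s encounter (only when the
    criterion has `use_encounter_period` and the encounter resolves to a
    period).

Clauses (a) and (b) combine as a **union**: a resource inside the day
window is matched even if the encounter period says otherwise, and vice
versa. The encounter clause exists because laboratory timestamps are often
unreliable, so the admission containing the triggering event is accepted as
a surrogate window; when the grounding resource has no encounter, only the
day window applies. All intervals are closed at both ends; windows are
converted to seconds (days × 86,400), so date-only and full timestamps mix
without surprises. Day windows may be `Inf`, in which case window mode
degenerates to ever mode restricted to *timed* grounding instances.

Two further fail-safe rules: base resources without an anchor time are
dropped (with a warning) whenever time is needed — a window criterion, a
calendar restriction, or an age bound — rather than silently passed; and a
criterion never matches through a dangling encounter reference.

These semantics are normative and enforced twice: once by the vectorised
engine, and once by an independent brute-force evaluator in the test suite
(plain nested loops over all (base, instance) pairs) that must agree with
the engine exactly on randomized stores and specifications.

## Feature tables and aggregation

The kept base resources become one row each: `patient_id`, `gender`, `age`,
`value`, `unit`, `code`, `time`. Age is computed at the row's own time, not
at extraction time, so a criterion like "aged 18–65" holds at measurement.
Optional per-patient aggregation reduces the table to one row per patient:

* `min_per_patient` / `max_per_patient` — extreme value; ties broken by
  earliest time, then smallest `fhir_id`; patients with only missing values
  are dropped with a warning;
* `first_per_patient` — earliest time, then smallest `fhir_id`;
* `random_one_per_patient` — one uniform draw per patient. The draw for
  patient `p` is made from a random stream seeded by a hash of
  `(random_seed, p)`, not from one global stream, so adding or removing
  other patients never changes `p`'s draw, and results are bit-stable
  across platforms.

Everything downstream is an ordinary tibble; output is RFC 4180 CSV with
ISO 8601 times.

## The synthetic hospital generator

Real hospital exports cannot ship with a package, so the generator emulates
the *shape* of one: patients with gender and birth date; encounters with
periods; ICD-10-coded Conditions; OPS-coded Procedures; LOINC-coded
laboratory Observations with numeric values and units. Every clinical event
is timestamped inside one of its patient's encounter periods and carries
the encounter reference — so encounter-period matching is exercised by
construction, not by luck. Codes are drawn as a configured prefix plus a
short random suffix ("C" → "C52.7"), which keeps prefix matching
nontrivial.

The default configuration (`default_synth_config()`) uses 2,000 patients
over 2016–2018, a Poisson(3) encounter process with 1–14-day stays, a
hemoglobin panel (718-7, g/dL; male 15.0 ± 1.1, female 13.4 ± 1.0), a
potassium panel (2823-3, mM; 4.0 ± 0.4), 15% malignancy prevalence, and two
injected effects: hemoglobin shifted by −2.5 g/dL in patients with a `C*`
condition, and potassium shifted by −0.4 mM within 7 days of an
amphotericin B administration (OPS `6-002.q*`). The baselines are invented
but physiologically plausible; nothing in the package's validation depends
on their absolute values — tests assert only the *recovery of configured
effects* (differences of means within standard-error bounds, sign
reproduction across seeds) and structural properties (references resolve,
labels match an independent interval scan, byte-identical regeneration
under a fixed seed).

What passing tests on synthetic data do **not** show: robustness to the
messiness of real exports — missing or contradictory timestamps at scale,
local coding quirks, unit heterogeneity, informative missingness, multiple
codings per concept. The generator emits clean, well-referenced resources
by design; real-data behaviour is bounded by the fail-safe rules above, not
demonstrated by these tests.

## The three worked scenarios

* **Anemia in malignancy** — per gender, each patient's *minimum*
  hemoglobin; patients split by an ever-mode `C*` criterion (include vs
  exclude); adults only (age ≥ 18 at the time of the minimum — the
  anchoring of "adult" at the minimum's own time is this package's
  reading); WHO thresholds 13 g/dL (men) / 12 g/dL (women), strict
  inequality; Fisher exact test per gender. Percentages are rounded
  half-up to one decimal. The same arithmetic can be fed with pre-tabulated
  group counts (`anemia_report_from_counts()`), and with the published
  counts shipped as `example_anemia_counts()` it reproduces 69.6% / 62.8%
  (men / women with cancer) versus 35.5% / 42.0% (without), both Fisher
  p < .001.
* **Reference-interval preparation** — hemoglobin of men 18–65, excluding
  `C*` ever, transfusion (`8-80*`) ever, hemoglobin < 8.0 g/dL ever, and
  surgery (`5-*`) within 90 days; one random finding per patient. The
  package reports a *naive* 2.5/97.5 percentile band of the surviving
  values, clearly labelled as a demonstration stand-in: a proper indirect
  reference-interval method (mixture deconvolution) is out of scope, and
  the feature table is exactly the dataset such a method would consume.
* **Potassium under amphotericin B** — study group: potassium observations
  within a 7-day window (either side) of an administration; control group:
  observations of patients who received the drug ever but contribute
  nothing to the study set. The patient-level set difference is applied
  first, then observations are collected, so the groups share no patient.
  Means are compared with Welch's two-sided t-test (the test choice is this
  package's, and is named in the report).

Two readings were genuinely open and are fixed here: "within 7 days" (and
"within 90 days") is a *symmetric* closed window — the weakest reading of an
undirected phrase; and code prefixes are matched against codes *as stored*,
with no dot-stripping or normalisation, which belongs in upstream ETL.

## Numerical choices

* Percentages round half-up (not banker's rounding) to one decimal,
  matching how such results are conventionally printed.
* The Fisher exact test sums hypergeometric probabilities no larger than
  the observed table's, computed via `lgamma` in log space, with a `1e-7`
  relative tolerance when comparing probabilities (ties would otherwise be
  lost to floating point). It is verified in the tests against exhaustive
  enumeration for every 2×2 table with total n ≤ 40 and against
  `stats::fisher.test` on random tables; those checks are cross-checks
  only — the implementation stands alone.
* The naive reference band uses the default quantile estimator
  (`stats::quantile`, type 7).
* Ever-mode criteria are cached per patient; window criteria are evaluated
  per (base, instance) pair through a patient-keyed join. Criteria are
  applied in listed order for the audit trail (removals per criterion sum
  to `n_base − n_kept`), while the kept set itself is order-independent.

## Problem sizes

The shipped validation uses desk-scale data chosen to exercise every code
path: 2,000-patient synthetic stores (~34,000 resources) for the scenario
and recovery tests, ten generator seeds for effect-recovery checks,
20-patient randomized stores for 50+ engine-vs-oracle equivalence cases,
and exhaustive Fisher enumeration up to n = 40. These sizes are the
package's own validation choices; the engine itself is vectorised and
handles larger stores linearly in resources per criterion.

## Known limitations

* One base selector per specification: no joint extraction of multiple
  analytes into one wide table.
* Conjunction-only criteria; no OR or NOT across criteria.
* No cohort/feasibility counting mode — the unit of filtering is the
  individual base resource, not the patient (distinct patients can of
  course be counted downstream).
* The in-memory store targets datasets of up to a few hundred thousand
  resources; it is a contract-faithful stand-in for a server-side
  document database, not a replacement for one.
* The encounter-period clause trusts encounter periods; incorrect periods
  in source data translate directly into matching decisions.
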
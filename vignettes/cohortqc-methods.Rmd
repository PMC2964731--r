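---
title: "Auditing clinical-research records for omission errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing clinical-research records for omission errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortqc)
```

## The problem

Clinical research registries are filled in by hand, field by field, from
narrative source documents. Omitted data — a field left empty although the
true value exists and could have been recorded — are more common than
wrongly inserted data, and they are the more dangerous kind: an empty
relapse-date field is indistinguishable from "the cancer never relapsed",
so omissions are usually *not* missing-at-random and can silently bias
time-to-event and outcome analyses. Omissions concentrate in *cognitively
isolated* fields, whose content is not logically tied to neighbouring
fields, and they cluster within records: a carelessly entered record tends
to be missing several things at once.

`cohortqc` implements a read-only auditing layer for such registries. Its
three pillars are:

1. a **record model** with explicit three-valued missingness,
2. a **possible-error rule engine** plus a three-section **record
   summary** that surfaces cross-field inconsistencies to the person
   entering the data, and
3. the **statistics** used to quantify omission prevalence, co-occurrence
   and the effectiveness of a summary-screen intervention, together with a
   **synthetic cohort generator** that makes every claim testable without
   access to patient data.

## Three-valued missingness

A single overloaded NULL is a classic registry design flaw: an empty
relapse-date cell may mean *no relapse happened* or *a relapse happened on
an unknown date*. The model therefore forces every nullable field into one
of three states — `present` (with a payload), `unknown`, `not_applicable`
— and keeps them distinct in memory, on disk (empty cell vs the literal
token `NA!`), and in rendered output (`UNKNOWN` vs `N/A`). Only the
`unknown` state is ever treated as a candidate omission; `not_applicable`
is a recorded answer.

```{r missingness}
fv_unknown()
fv_na()
```

## The record model and timelines

A `patient_record` holds identifiers, demographics, diagnosis fields,
outcome status and a table of dated clinical events (surgery with a
procedure code, radiation start/end with a planned course length,
chemotherapy, relapse, remission, follow-up, death). `build_timeline()`
orders diagnosis and events chronologically and reports every inter-event
span longer than a threshold (default 365 days) as a gap. Same-day ties
are broken by a fixed, clinically plausible order (diagnosis before
surgery before treatment starts; deaths last); any fixed total order would
do — what matters is that the timeline is a pure function of the record,
which a property test verifies by shuffling stored event order.

The loader treats the relapse-date field and relapse events as one
clinical fact: if only one side is present it materialises the other and
notes the repair in the load report.

## Possible-error rules

The rules encode the observation that *unexpected treatment activity* and
similar cross-field surprises usually mean something was omitted, not that
the surprise is real. Firings are deliberately *possible* errors — likely
but not certain — so they are listed non-interruptively and never block
entry. The built-in rules and their defaults:

| rule | predicate | parameters (default) |
|------|-----------|----------------------|
| R1 | a more radical surgery follows a less radical one with no relapse documented in the interval | `min_gap_days` (30), radicality table |
| R2 | documented remission + vital status "died from disease" + no relapse date | — |
| R3 | a treatment start ≥ `quiescence_days` after the previous episode ended, no relapse in between | `quiescence_days` (180) |
| R4 | a radiation course ends before `min_completion_fraction` of its planned duration | `min_completion_fraction` (0.8) |
| R5 | a key field is in the `unknown` state (`not_applicable` never fires) | `key_fields` (gender, dob, cancer_site, xrt_start) |

Parameter defaults are design choices, not published values: the source
setting gives no thresholds, so clinically plausible values were fixed
once and exposed in the configuration file (`load_rule_config()`), which
also lets a site disable rules and override the surgical radicality
ranking for non-breast databases. A relapse suppresses R1/R3 only when it
falls strictly after the earlier reference event and no later than the
flagged one — the relapse has to *explain* the new activity. For R3 a
treatment episode's end is its matching end event when recorded, else the
start date itself, since real registries often lack end dates. R4 uses a
strict inequality, so a course ending exactly at the completion threshold
does not fire. Unknown procedure codes make surgeries incomparable and R1
skips them.

The engine dispatches from a registry keyed by rule id, so additional
rules can be configured without touching the dispatch logic.

```{r rules}
rec <- patient_record(
  "B-0001",
  gender = fv_present("F"),
  diagnosis_date = fv_present(as.Date("2001-01-10")),
  relapse_date = fv_unknown(),
  events = dplyr::bind_rows(
    clinical_event("surgery", "2001-02-01", procedure_code = "lumpectomy"),
    clinical_event("xrt_start", "2001-03-01", planned_duration_days = 42),
    clinical_event("xrt_end", "2001-04-12"),
    clinical_event("surgery", "2002-10-01",
                   procedure_code = "modified_radical_mastectomy")
  )
)
apply_rules(rec)[, c("rule_id", "message")]
```

## The record summary

`render_summary()` produces the three-section document — verbatim key
fields, timeline with gap annotations, possible errors — as plain text or
static HTML (no scripting, so output is reproducible byte-for-byte). All
three sections are always present; empty ones render a placeholder, so a
reviewer can grep for the section headers unconditionally.

## Statistics

The analysis layer reproduces a standard omission study design:

* `classify_records()` splits a cohort on an *index field* (by default the
  radiation start date) into records with the field recorded, records
  missing it where manual review found no value (truly missing), and
  records missing it where review recovered the value (omission errors).
* `cooccurrence_analysis()` tabulates, per category, how often *probe
  fields* (gender, date of birth, cancer site) are also missing, with
  exact binomial (Clopper–Pearson) confidence intervals, per-field
  two-sided Fisher tests comparing the truly-missing against the
  omission-error category, Hochberg-adjusted companions, and the
  any-probe-field-missing composite rate.
* `effectiveness_analysis()` scores an access/edit trace log: a record is
  *accessed* if the summary screen was opened for it at least once and
  *corrected* if an edit moved the target field from `unknown` to a
  present value (overwrites of present values are tracked separately as
  revisions; edits with identical before/after are ignored with a
  warning). It reports the accessed × corrected contingency table,
  per-group proportions with exact CIs, the Fisher p-value, and how many
  corrections fell within an attribution window (default 10 minutes)
  after the latest preceding access.
* `utilization_summary()` reports the access-count histogram (0/1/2/3+),
  overall and new-vs-update access rates, and per-user rates.

The exact interval, the Fisher test and the Hochberg adjustment are
deliberately thin wrappers over `stats::binom.test()`,
`stats::fisher.test()` (probability-mass two-sided definition, not the
doubled one-sided p) and `stats::p.adjust(method = "hochberg")`; the test
suite checks each against an independently coded oracle — numeric
inversion of the binomial tail sums, exhaustive enumeration of all 2×2
tables with margins up to 12, and a direct evaluation of the step-up
formula. Degenerate inputs follow explicit conventions: a 2×2 table with
a zero margin carries no information and returns p = 1 with a warning;
an empty record category is emitted with n = 0 and undefined CI markers.

Percentages are displayed with half-up rounding to one decimal (R's
`round()` is half-even); raw values are retained alongside because
published tables are not always consistent about their own rounding.

Per-user utilization needs to know which records a user worked on, which
a bare access/edit trace schema does not state directly. The package
defines a user's workload as the records carrying any trace by that user,
and the generator guarantees the definition is meaningful by emitting at
least one field edit per data-entry session — a realistic assumption,
since entering or updating a record always edits something.

## The synthetic cohort generator

No patient-level data from the original registries are available, so the
generator is a first-class module rather than a test fixture. Its
defaults emulate the study conditions the analyses were designed for: a
registry of 1,356 records of which 200 are newly entered; three data-entry
users with access propensities 84.6%, 47.1% and 11.8% and workload shares
0.2/0.6/0.2; probe-field omission rates of 4–10%; an index-field split in
which about 10% of records have no recoverable radiation start date and a
further few percent have it omitted by error; relapse prevalence 25% with
30% of relapse dates omitted at entry; correction propensities of 0.30
given a summary access versus 0.05 without (the published figures report
the resulting correction margins, not the underlying propensities, so
these were fixed once at plausible values of that order); and lognormal
edit latencies with a 5-minute median, which produces both inside- and
outside-window attributions.

Omission clustering uses the simplest mechanism that reproduces the
co-occurrence finding: a two-point per-record "carelessness" multiplier
(default ×2.5 with probability 0.2) scaling all omission probabilities,
so records with an injected index-field omission are enriched for probe
omissions too. The event scaffold is diagnosis → surgery → optional
radiation course (with planned duration) → optional relapse with salvage
chemotherapy → death or censoring, with inter-event gaps drawn from fixed
plausible ranges; the source setting gives no event-timing distributions,
so these ranges are design choices.

`scenario_counts` rewrites a requested number of records into scenarios
that exactly satisfy each rule's predicate; every construction is
verified against the rule before emission and logged in the ground-truth
log, which is the oracle for the recall tests. `inject_omission()` /
`restore_omission()` give the same logged-truth mechanism for ad hoc
fixtures. All randomness flows from the single seed in the spec, and the
generator restores the caller's random stream, so runs are reproducible
byte-for-byte.

What the generator does **not** model: real breast/sarcoma clinical
distributions, co-morbidities, multi-diagnosis records, or user learning
over time. Passing tests therefore demonstrate correctness of the
machinery under controlled error structure, not performance on any real
registry.

## Problem sizes used by the test suite

The serialization round-trip property runs on 1,000 generated records;
omission-rate recovery on 10,000; clustering direction on 40 seeds of 400
records; the Fisher enumeration on all ~6,000 valid 2×2 tables with
margins ≤ 12; interval coverage on 10,000 simulated draws at p = 0.1,
n = 118; the Hochberg oracle on 1,000 random vectors; rule recall on 50
injected scenarios per rule; and the co-occurrence power check on 100
seeds at the published category sizes (226 vs 118). The power check uses
the any-probe-field-missing contrast: at the published per-field rates
the single-field Fisher tests have power between roughly 20% and 80% at
these sample sizes, while the composite — which is also the headline
co-occurrence claim — rejects in well over 80% of seeds.

## Known limitations

* The full original rule catalogue is not public; the engine ships the
  rules that are documented and a configuration path for adding more.
* Regression modelling of access and correction predictors is out of
  scope: it requires the original patient-level data.
* Record-level overlap between probe-field omissions cannot be recovered
  from published marginals; `cohort_from_marginals()` fixes an arbitrary
  deterministic overlap, which reproduces every marginal count but not
  any-field-missing composites of the original data.
* The CLI is a thin dispatcher (`exec/cohortqc`) over the exported
  `cmd_*()` functions; exit codes are 0 (success), 2 (input error),
  1 (unexpected failure).
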
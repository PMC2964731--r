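# cohortqc

Data-quality auditing for longitudinal clinical-research records.

Registries in clinical research are filled in by hand from narrative
source documents, and the most dangerous entry error is the *omission*: a
field left empty although the true value exists. An empty relapse-date
field reads as "no relapse", so omissions are rarely missing-at-random and
can bias outcome analyses outright. They concentrate in cognitively
isolated fields and cluster within carelessly entered records.

`cohortqc` is for registry maintainers and methods researchers who want to
find and quantify those omissions. It provides:

* a record/event data model with **three-valued missingness** — `present`,
  `unknown`, `not_applicable` — kept distinct in memory, on disk (empty
  cell vs the `NA!` sentinel) and in rendered output (`UNKNOWN` vs `N/A`);
* a configurable cross-field **possible-error rule engine** (escalated
  surgery without documented relapse, death from disease without a relapse
  date, unexpected late treatment activity, abruptly discontinued
  radiation courses, missing key fields);
* a three-section **record summary** (verbatim key fields, clinical
  timeline with gap annotations, flagged possible errors) as text or
  static HTML;
* the **omission statistics**: record classification by index-field
  missingness and manual review, co-occurrence tables with exact binomial
  (Clopper–Pearson) confidence intervals, two-sided Fisher's exact tests,
  Simes–Hochberg adjustment, access/edit-trace effectiveness and
  utilization analyses;
* a **synthetic cohort generator** with clustered omissions, rule-exact
  injected scenarios, user access/edit traces and an exhaustive
  ground-truth log.

The statistical core, in the field's usual notation: for `x` missing
fields among `n` records the exact interval inverts the binomial tails,
`(p_L, p_U)` with `P(X ≥ x | p_L) = α/2` and `P(X ≤ x | p_U) = α/2`;
association between missingness and record category uses the two-sided
Fisher probability-mass test on the 2×2 table; families of per-field tests
are adjusted by the Hochberg step-up rule `p̃_(k) = min(1, min_{j≥k}
(m−j+1) p_(j))`.

## Worked example

A breast-cancer record: lumpectomy, adjuvant radiation, then — after an
18-month quiet stretch — a modified radical mastectomy, with no relapse
recorded anywhere:

```r
library(cohortqc)

rec <- patient_record(
  "B-0001",
  gender = fv_present("F"),
  dob = fv_present(as.Date("1950-05-01")),
  cancer_site = fv_present("breast"),
  diagnosis_date = fv_present(as.Date("2001-01-10")),
  tumor_grade = fv_present("moderate"),
  t_stage = fv_present("T1"),
  relapse_date = fv_unknown(),
  events = dplyr::bind_rows(
    clinical_event("surgery", "2001-02-01", procedure_code = "lumpectomy"),
    clinical_event("xrt_start", "2001-03-01", planned_duration_days = 42),
    clinical_event("xrt_end", "2001-04-12"),
    clinical_event("surgery", "2002-10-01",
                   procedure_code = "modified_radical_mastectomy")
  )
)
cat(render_summary(rec, apply_rules(rec)))
```

```
== KEY FIELDS ==
record_id: B-0001
gender: F
dob: 1950-05-01
cancer_site: breast
diagnosis_date: 2001-01-10
tumor_grade: moderate
t_stage: T1
vital_status: unknown
relapse_date: UNKNOWN

== TIMELINE ==
DATE        EVENT
2001-01-10  DIAGNOSIS
2001-02-01  SURGERY (lumpectomy)
2001-03-01  XRT_START (planned 42d)
2001-04-12  XRT_END
── gap: 537 days ──
2002-10-01  SURGERY (modified_radical_mastectomy)

== POSSIBLE ERRORS ==
[R1] more radical surgery (modified_radical_mastectomy on 2002-10-01) after earlier less radical surgery with no documented relapse in between; relapse date possibly omitted {event:surgery@2002-10-01; relapse_date}
[R3] treatment activity (surgery) resumed 537 days after the previous treatment episode with no documented relapse; relapse information possibly omitted {event:surgery@2002-10-01; relapse_date}
```

The escalation from lumpectomy to mastectomy with an `UNKNOWN` relapse
date is exactly the pattern that usually means the relapse date was
omitted — flagged as *possible*, never blocking, because a patient may
genuinely have requested the more radical procedure.

The statistics work the same way from code or from the CLI
(`exec/cohortqc` with subcommands `audit`, `summarize`, `cooccurrence`,
`effectiveness`, `simulate`):

```r
clopper_pearson_ci(18, 226)
#>       low      high
#>  4.788534 12.295499        # 4.8–12.3% missing gender among 226 records
fisher_exact_2x2(matrix(c(16, 446, 4, 690), 2, 2, byrow = TRUE))
#> [1] 0.0003134479           # corrections: 16/462 accessed vs 4/694 not
```

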
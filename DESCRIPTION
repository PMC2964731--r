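Package: cohortqc
Title: Data-Quality Auditing for Longitudinal Clinical Research Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects likely errors of omission in clinical-research registry
    records. Provides a three-valued missingness data model for patient
    records and treatment events, a configurable cross-field "possible
    error" rule engine (escalated surgery without documented relapse,
    death from disease without a relapse date, unexpected late treatment
    activity, abruptly discontinued radiation courses, missing key
    fields), a read-only three-section record summary renderer (key
    fields, clinical timeline, flagged possible errors), omission
    prevalence and co-occurrence statistics with exact binomial
    confidence intervals, Fisher's exact test and Hochberg step-up
    adjustment, an access/edit-trace effectiveness analysis, and a
    synthetic cohort generator with ground-truth injected errors for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
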
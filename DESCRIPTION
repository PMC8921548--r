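Package: vustriage
Title: Constraint-Metric Variant Triage for Cardiomyopathy Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting rare variants from diagnostic
    cardiomyopathy gene panels with population constraint metrics. Computes
    case-excess scores and etiological fractions (EF) from carrier burden
    counts with exact tests and confidence intervals, applies gnomAD-style
    gene intolerance screens (pLI, missense Z), assigns EF-banded ACMG
    evidence criteria and combines them into five-tier classifications,
    triages variants of uncertain significance into reclassification or
    prioritization, validates concordance against prior likely-pathogenic
    calls, and reports cohort-level diagnostic yield. Includes a seeded
    synthetic-cohort generator and a deterministic packaged fixture for
    end-to-end pipeline exercise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
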
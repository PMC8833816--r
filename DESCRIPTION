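Package: ovtriage
Title: Pre-Operative Triage of Pelvic Masses with IOTA Simple Rules, ROMA and
    RMI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule-based pre-operative triage of adnexal (pelvic) masses and
    paired evaluation of its diagnostic performance.  Implements the IOTA
    simple-rules three-way ultrasound classifier, the Risk of Malignancy
    Algorithm (ROMA) on serum HE4 and CA125, the Risk of Malignancy Index
    (RMI), an expert-assessment fallback for inconclusive simple-rules
    results, and the five combined triage strategies built from them.
    Provides two-by-two diagnostic tables with exact (Clopper-Pearson) and
    Wilson confidence intervals, paired McNemar comparisons between
    strategies, subgroup analyses, a simulation-based power calculation for
    paired non-inferiority designs, and a synthetic-cohort generator with
    closed-form operating points so the whole pipeline can be exercised and
    calibrated without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
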
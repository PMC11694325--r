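Package: pvdisprop
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance toolkit for FAERS-shaped
    spontaneous adverse-event report data, built around tumor adverse events
    reported under proton-pump-inhibitor exposure. Provides a synthetic
    report generator with planted reporting-odds-ratio structure, the
    standard report deduplication and exclusion cascade (latest FDA_DT,
    delete files, age and weight range filters, suspect-role restriction),
    a compact MedDRA-style PT/HLT/HLGT/SOC hierarchy with tumor-term
    classification, reporting odds ratio (ROR) disproportionality scans with
    Wald confidence intervals and the three-case signal criterion,
    descriptive case summaries with group-comparison tests, Kaplan-Meier
    time-to-onset analysis, and univariate logistic risk-factor models over
    age, sex, drug and daily-dose bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
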
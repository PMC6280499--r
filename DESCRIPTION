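Package: adeprev
Title: Preventability Assessment of Adverse Drug Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for assessing the preventability of adverse drug events
    (ADEs) in chart-review studies. Implements a modified Schumock-Thornton
    preventability algorithm as a deterministic rule engine over Yes/No/
    Uncertain criterion responses, a dual-reviewer consensus workflow with
    third-reviewer adjudication, agreement statistics (Cohen's kappa with
    asymptotic 95% confidence intervals, binomial proportions with Wald or
    Wilson intervals, binary collapse of the three-level preventability
    scale), criterion-attribution frequency tables, and a seeded synthetic
    rater-cohort generator with latent true preventability and per-rater
    misclassification, so the full pipeline can be exercised and tested
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
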
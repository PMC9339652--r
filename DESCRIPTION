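Package: npdecline
Title: Regression-Based Change Norms and Dementia Prognosis from Serial
    Neuropsychological Exams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies 12-month neuropsychological (NP) decline in older
    adults using regression-based change norms that absorb practice effects
    and regression to the mean. Ships a published six-test norm set
    (Logical Memory I/II, Trail Making A/B, Animals, Vegetables), computes
    per-subtest and composite NP decline z-scores with a published ROC
    cutoff, and evaluates NP decline as a predictor of incident all-cause
    dementia via conversion contrasts, factorial ANCOVA, Cox proportional
    hazards models, and stratified cumulative-progression curves. Includes
    a synthetic longitudinal cohort simulator so the whole pipeline is
    testable without access-controlled registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    car,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
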
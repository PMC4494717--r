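Package: bronchlus
Title: Lung Ultrasound and Clinical Severity Scoring for Infant Bronchiolitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grading infant bronchiolitis from bedside observations
    and lung ultrasound (LUS) findings, and for evaluating how well the two
    assessments agree. Implements a four-item clinical severity score (0-12)
    and a four-component LUS score (0-8) with ordinal severity banding, an
    oxygen-need classification rule based on the LUS total, Cohen's kappa
    with its large-sample null standard error and z test, diagnostic accuracy
    metrics (sensitivity, specificity, predictive values) with Wilson and
    Clopper-Pearson binomial confidence intervals, and Pearson chi-squared
    comparisons of finding frequencies between patient groups. A seeded
    synthetic-cohort generator emulates the marginal and conditional
    structure of a published bronchiolitis cohort so every analysis stage is
    testable without patient data, and packaged fixtures carry the printed
    contingency counts of that study for end-to-end reproduction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
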
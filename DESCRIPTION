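Package: pwvrec
Title: Individualized Antihypertensive Recommendation Modelling for
    Arterial Stiffness Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating per-drug-class outcome models
    of pulse wave velocity (PWV) change in treated hypertensive cohorts, and
    for turning them into individualized antihypertensive recommendations.
    Provides a synthetic multicohort generator with known heterogeneous
    treatment-effect functions, median-imputation and PWV-standardization
    preprocessing, per-arm random-forest counterfactual models with
    impurity- and permutation-based feature selection, SMOTE-style training
    augmentation for external validation, argmax treatment recommendation
    with match-rate summaries, and an interpretable surrogate decision tree
    distilled from the recommendation policy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
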
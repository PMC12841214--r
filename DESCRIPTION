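Package: fallrisk
Title: Instrumented Fall-Risk Stratification for Post-Stroke Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a three-stratum (low/medium/high) fall-risk scale from a
    subjects-by-features table of instrumented Timed-Up-and-Go (ITUG) and
    clinical measures, and evaluates any such scale against observed fall
    status. Feature selection runs a consensus procedure over repeated
    balanced subsamples of the training split, gated by a support-vector
    machine accuracy criterion on a held-out validation split, with
    normality-routed two-group tests per feature. Scale construction stores
    tertile cut-points of the ranked training values per selected feature;
    new subjects are stratified per feature and combined by the mode with
    ties resolved to the higher risk stratum. Evaluation uses the exact
    Fisher-Freeman-Halton test on 2x3 fall-status by stratum contingency
    tables. Includes a synthetic cohort generator with planted group
    effects and Gaussian minority-class augmentation, bundled
    literature-threshold rules for eight clinical comparator scales, and a
    command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
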
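Package: avstraj
Title: Screening Validation and Longitudinal Trajectory Phenotyping for
    ECG-Derived Aortic Stenosis Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating a continuous ECG-derived aortic stenosis
    score as a community screening test and as a longitudinal biomarker
    before transcatheter aortic valve replacement (TAVR). Implements
    ROC/Youden cutpoint analysis with Bayes prevalence-adjusted predictive
    values, false-positive prognosis survival contrasts, EM clustering of
    irregular score trajectories with thin-plate spline centroids (with BIC,
    silhouette, and adjusted-Rand stability diagnostics), Cox mortality
    modelling by trajectory cluster, Harrell's C-index and categorical net
    reclassification improvement with bootstrap confidence intervals,
    threshold first-crossing summaries, and a synthetic cohort generator
    that emulates the statistical structure of both study populations.
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
    mgcv,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
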
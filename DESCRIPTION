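Package: planqc
Title: Plan-Quality Evaluation and Robustness Comparison for Automatic
    Radiotherapy Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dose-volume histogram computation, conformity and homogeneity
    indices, piecewise-linear plan-quality-metric (PQM) scoring and paired
    nonparametric cohort comparison for volumetric-modulated arc therapy
    plans of the pelvis. Ships a synthetic pelvis-phantom cohort generator
    with strategy-dependent dose models (manual, script-based and hybrid
    automatic planning at easy, moderate and hard clinical-goal settings),
    a prediction-driven clinical-goal update workflow with ring-structure
    and additional organ-at-risk goals, and the statistical protocol
    (paired t-test or Wilcoxon signed-rank chosen by a Shapiro-Wilk
    normality check) used to compare planning strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
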
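Package: orbitdx
Title: Panel Gene-Expression Scoring for Orbital Inflammatory Disease and Lymphoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating non-specific orbital inflammation (NSOI),
    IgG4-related orbital disease (IgG4-ROD) and orbital MALT lymphoma from
    NanoString nCounter-style panel counts. Implements negative-control
    background normalization, reference-gene (housekeeping) normalization and
    basal-noise filtering; group-versus-rest differential expression with a
    Shapiro-Wilk-gated t/Wilcoxon test and false-discovery-rate adjustment; a
    permutation-based conditional-inference-tree learner for marker and
    cut-off discovery; the three published binarized multi-gene diagnostic
    scores with their cut-offs; nonlinear logistic risk models mapping scores
    to entity risk; and ROC/AUC evaluation with stratified bootstrap
    confidence intervals. A negative-binomial cohort simulator reproduces the
    screening (12-sample) and validation (48-sample) study designs so the full
    pipeline can be exercised end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
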
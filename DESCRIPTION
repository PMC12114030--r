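Package: komet
Title: Human Knockout Metabolic Outlier and Disease Association Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for association analysis between rare predicted
    loss-of-function (pLoF) gene knockouts and untargeted plasma metabolite
    profiles in biobank cohorts. Implements two gene/variant selection
    strategies on annotated variant tables, a two-stage covariate adjustment
    producing normalized residual metabolite values, exact one-sided Wilcoxon
    rank-sum scans suited to extreme group imbalance, an effective-number-of-
    tests Bonferroni threshold from principal components, Fisher tests for
    below-detection-limit missingness, simulation-based power analysis, and
    stratified conditional exact variant-disease tests with conditional
    maximum-likelihood common odds ratios from electronic health records.
    Includes a synthetic cohort generator so the full pipeline is testable
    without access-restricted individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    ggplot2,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
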
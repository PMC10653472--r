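Package: mirf
Title: Multiview Iterative Random Forests for Multi-Omics Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Feature and interaction discovery from multiview omics data
    (gene expression plus protein expression) with iteratively reweighted
    random forests and generalized Random Intersection Trees under three
    nested layers of bootstrap resampling. Persistent features are selected
    by Gini-importance and replicate-persistence thresholds; signed
    interactions are scored by bagged stability. Downstream validation
    covers Kaplan-Meier curves with log-rank tests, elastic-net Cox
    regression with concordance-selected penalty, univariate and
    multivariate Cox models with backward stepwise selection, and
    signature-score patient stratification with expression-mean cutoffs.
    A synthetic two-omics cohort generator with planted Boolean signal,
    Weibull proportional-hazards survival and MCAR missingness provides
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    survival,
    glmnet,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr
Config/testthat/edition: 3
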
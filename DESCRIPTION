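Package: drbench
Title: Bias-Aware Benchmarking of Drug Response Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmarking harness for models that predict continuous drug
    response (ln IC50, IC50, EC50, pEC50, AUC) of cancer cell lines. Provides
    application-specific cross-validation splits (leave-pair-, leave-cell-line-,
    leave-tissue- and leave-drug-out) with strict group disjointness, a family
    of naive mean-effect baselines that expose Simpson's-paradox inflation of
    global metrics, mean-effects-normalized evaluation metrics, Friedman and
    Conover rank statistics with critical-difference grouping, feature-ablation
    randomizers (permutation, moment-preserving Gaussian, degree-preserving
    edge shuffle), cross-study evaluation with overlap exclusion,
    replicate-aware dose-response curve fitting with validity filtering, and
    synthetic-data generators so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    minpack.lm,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
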
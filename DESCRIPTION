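Package: consensusdeg
Title: Consensus Differential-Expression Meta-Analysis Across Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-cohort transcriptomic meta-analysis by direction-consistent
    vote counting. Runs per-dataset differential expression on log2 expression
    matrices, tallies up/down calls across many datasets grouped by disease,
    and classifies genes as common or disease-unique "winning" biomarkers.
    Includes coexpression-network construction with clustering-coefficient
    threshold selection, common-connectivity-pattern detection between
    networks, hypergeometric over-representation analysis against GMT gene
    sets, Kaplan-Meier/log-rank screening of expression-dichotomized survival,
    and a seeded synthetic-data generator with planted effects for validating
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
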
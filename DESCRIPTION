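Package: tcgsa
Title: Time-Course Gene Set Analysis with Mixed-Effects Likelihood Ratio Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hypothesis-driven gene set analysis for longitudinal gene
    expression data. Each a-priori gene set is modelled with a gene-set-level
    linear mixed model in which every time coefficient splits into a fixed
    set-level trend and a gene-level (or patient-level) random deviation.
    Whether a set changes over time (one-group design), or changes
    differently between treatment groups, is tested by a joint likelihood
    ratio test of the fixed and random trend terms against a
    chi-square-mixture null that accounts for the variance-component
    boundary. False discovery rate control defaults to Benjamini-Yekutieli.
    Significant heterogeneous sets are decomposed into trends via BLUP
    trajectory prediction, Ward hierarchical clustering and the gap
    statistic. A simulation module generates longitudinal expression data
    with the same statistical structure and drives type-I error / power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
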
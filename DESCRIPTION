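Package: gutkeystone
Title: Keystone Taxa, Co-Abundance Networks, and Cross-Cohort Gut
    Microbiome Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for cross-cohort gut-microbiome
    epidemiology built around a natural-experiment exposure (early-life
    famine) and a binary disease outcome (type 2 diabetes).  Provides
    compositional preprocessing (sample/prevalence filters,
    multiplicative zero replacement, centered log-ratio transform),
    alpha-diversity indices with per-cohort standardisation, Bray-Curtis
    community structure analysis (principal coordinates, PERMANOVA with
    pairwise Benjamini-Hochberg adjustment), co-abundance network
    inference by three estimators (Pearson on CLR, SparCC, and
    neighborhood-selection sparse inverse covariance with StARS
    stability selection), eigenvector-centrality keystone-taxon calling
    and a shared keystone-taxa index, covariate-adjusted linear and
    logistic association models, and DerSimonian-Laird random-effects
    meta-analysis.  A synthetic multi-cohort generator with planted hub
    networks and planted exposure effects makes the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    ape,
    picante,
    igraph,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
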
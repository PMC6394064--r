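Package: uromark
Title: Discovery and Verification of Urinary Kidney-Specific mRNA Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering urinary kidney-specific mRNA
    biomarkers from multi-tissue expression compendia and verifying them in
    clinical cohorts. Pools multi-platform log2 expression matrices onto a
    shared feature space, applies quantile normalization with median-polish
    summarization and matrix-level quality control (relative log expression
    screening, PCA-based batch detection), selects differentially expressed
    genes per contrast with an empirical-Bayes moderated t-statistic and
    Benjamini-Hochberg adjustment, and screens cross-tissue candidates by
    two co-differential rules with a low-expression confounder filter.
    Clinical verification covers delta-Ct relative expression, fold change
    of group medians, Kruskal-Wallis and pairwise rank tests, Spearman
    correlation, ROC analysis with Youden-index cutoffs, and replicate
    coefficient-of-variation reports. Includes synthetic-data generators
    with known planted truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC
Config/testthat/edition: 3
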
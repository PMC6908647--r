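Package: methpanel
Title: Discovery and Evaluation of Cancer-Type-Specific DNA Methylation
    Marker Panels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative DNA-methylation and gene-expression analysis
    toolkit for discovering cancer-type-specific methylation markers from
    Illumina 450K-style beta-value arrays and RNA-seq counts. Provides
    probe-level quality control, Wilcoxon rank-sum differential methylation
    with exact small-sample enumeration, TMM-normalised negative-binomial
    differential expression, consensus K-means clustering of CpG island
    methylator phenotypes, methylation-expression correlation, cross-cancer
    specificity screening, and hybrid feature selection (information gain
    followed by sequential backward selection) with ridge-logistic
    cross-validated evaluation. A synthetic multi-cancer cohort generator
    with planted ground truth makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
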
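Package: locusdissect
Title: Integrative Dissection of a GWAS Risk Locus from Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting a single GWAS risk locus from summary
    statistics: Bayesian fine-mapping with a sum-of-single-effects model on
    z-scores and an LD correlation matrix, credible-set retention and
    credible-causal-variant union rules, COJO-style conditional association,
    approximate-Bayes-factor colocalization of GWAS and QTL signals,
    summary-based transcriptome-wide association (TWAS) with conditional and
    joint gene models, chromatin-state and capture-HiC variant-to-gene
    nomination, and tumor-cohort analyses (RAS-MAPK mutation-model
    classification, covariate-adjusted expression association, Firth-penalized
    Cox survival, and sample-size-weighted z-score meta-analysis). A
    synthetic-data module generates every input with known ground truth so the
    whole pipeline is testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    rtracklayer,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
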
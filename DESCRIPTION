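Package: duomics
Title: Integrative Transcriptome-Proteome Differential Expression and
    Co-Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating bulk RNA-seq and 2D-gel proteomics from
    factorial (genotype by treatment) designs. Implements consensus
    differential-expression calling across multiple simplified callers
    (negative-binomial Wald and likelihood-ratio tests, log-scale t-test),
    2D-gel spot-volume normalization and Student's t testing with
    spot-to-gene redundancy accounting, permutation tests for the overlap of
    feature sets drawn from linked universes with an exact hypergeometric
    oracle, a weighted co-expression procedure (soft-threshold adjacency,
    topological overlap, module detection, eigengenes, module-trait
    correlation, thresholded edge export, module-membership permutation
    test), Fisher's-exact GO enrichment with an optional elim-style
    decorrelation, qPCR delta-delta-Ct quantification, and a synthetic-data
    generator that plants recoverable ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
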
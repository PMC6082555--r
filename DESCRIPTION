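Package: uqpgq2
Title: Gene-Wise Normalization and False-Positive-Controlled Differential
    Expression for RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression analysis of bulk RNA-seq count data with
    an emphasis on specificity. Implements the two-stage UQ-pgQ2 normalization
    (per-sample upper-quartile scaling followed by per-gene scaling to the
    across-sample median), median-of-ratios size factors, a negative-binomial
    Wald test with dispersion trend and empirical-Bayes shrinkage, a mock
    within-group comparison procedure that selects |log2 fold change| cutoffs
    by empirical false-positive rate, a rule combining the calls of two
    normalization routes into a high-confidence gene set, and a negative
    binomial count simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
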
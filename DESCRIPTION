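Package: omnifisher
Title: Gene-Level Multi-Omics Association Tests via Covariance-Adjusted
    Fisher Combination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Gene-level association testing for traits against up to three
    omics layers (SNP genotypes, DNA methylation M-values, RNA expression)
    using kernel-machine variance-component score tests, with the per-layer
    p-values combined into a single gene-level p-value by a Fisher statistic
    whose null distribution is Satterthwaite-adjusted for the empirical
    covariance between the layers' p-values.  The covariance is estimated by
    perturbation of the score statistics with shared per-subject normal
    draws, which also drives an optimal (minimum-p over all seven layer
    combinations) test calibrated by resampling.  Includes synthetic-data
    generators (LD-structured haplotypes, block-correlated methylation,
    expression pools) and Type I error / power simulation harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    vcfR
Config/testthat/edition: 3
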
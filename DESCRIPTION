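Package: clonalGBLUP
Title: Multi-Kernel GBLUP Decomposition of Additive and Nonadditive
    Variance in Clonally Replicated Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-enabled decomposition of quantitative-trait variance in
    clonally replicated multi-site trials into additive, dominance, and
    additive-by-additive epistatic components, with genotype-by-site
    interactions.  Builds VanRaden-style additive, dominance, and Hadamard
    epistatic genomic relationship matrices alongside pedigree counterparts,
    fits the multi-kernel mixed model by average-information REML with
    expectation-maximization fallback, derives narrow- and broad-sense
    heritability and the between-site genotypic correlation, and evaluates
    genomic prediction accuracy and bias by leave-one-family-out
    cross-validation under two masking strategies.  Includes a synthetic
    clonal-trial generator (pedigreed full-sib families, gene drop over
    unlinked SNPs, configurable variance architecture) with known ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
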
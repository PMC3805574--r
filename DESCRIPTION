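Package: haplohwe
Title: Haplotype-Based Hardy-Weinberg Equilibrium Tests for Tightly Linked SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood haplotype frequency estimation from unphased
    genotypes of unrelated individuals under three population models (random
    union of gametes, an excess-homozygosity model with a single multiplicative
    parameter, and an inbreeding model with coefficient f), via EM,
    expectation-conditional-maximization (ECM) and an augmented-data EM (IEM).
    Provides two one-degree-of-freedom likelihood-ratio tests of haplotype-based
    Hardy-Weinberg equilibrium, a simulation engine for size/power/accuracy
    studies, and readers for linkage pedigree (PED) files with haplotype-block
    definitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
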
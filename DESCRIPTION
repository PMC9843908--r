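Package: kinfer
Title: Kinship and IBD Inference from Low-Coverage Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hidden-Markov-model inference of pairwise relatedness (up to the
    third degree, distinguishing siblings from parent-child) and the genomic
    location of identity-by-descent (IBD) tracts from low-coverage diploid
    sequencing data, such as ancient DNA. Works directly on per-site read
    counts over a fixed set of biallelic sites, without genotype calls or an
    external allele-frequency panel. Includes a companion two-state HMM for
    detecting long runs of homozygosity (ROH), a heuristic correction for
    present-day DNA contamination, analytic and simulation-based IBD
    transition matrices, and a pedigree simulator with known truth used for
    transition-matrix estimation and method validation.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
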
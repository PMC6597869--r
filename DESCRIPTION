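Package: incursr
Title: Genetic Source Tracing of Insect Incursions from Genome-Wide SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracing the source populations of invasive insects
    intercepted at international borders, using genome-wide biallelic SNP
    genotypes. Implements the full analysis chain: quality filtering of a
    genotype matrix (per-group call rate, minor allele frequency,
    Hardy-Weinberg exact test, physical-distance thinning, individual
    missingness, Loiselle kinship pruning and population capping),
    delineation of reference populations by Monte Carlo cross-validation
    with composite-population merging, individual assignment by cluster
    detection on principal components across a BIC/AIC-bounded range of K
    and by a linear support vector machine with calibrated posterior
    probabilities, a combined assignment-confidence classification, and
    classification of knockdown-resistance (kdr) genotypes at the
    voltage-sensitive sodium channel gene. A Balding-Nichols simulator
    generates structured reference panels with known truth so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
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
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
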
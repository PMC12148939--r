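Package: evoreseq
Title: Repeatability of Thermal Adaptation in Evolve-and-Resequence
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of evolve-and-resequence experiments on thermal
    adaptation across replicated genetic backgrounds. Provides a
    Wright-Fisher drift null for pool-seq allele-frequency change (the
    classical beta approximation plus a sampling-aware refinement that
    models pooling and read-depth noise), temporal estimation of the
    variance effective population size, logit-slope selection
    coefficients, mean-scaled change-vector geometry (pairwise angles
    with shared-ancestor error correction, convergence/divergence,
    evolutionary rates, Monte-Carlo and permutation nulls) applied
    identically to trait and allele-frequency space, pleiotropy
    classification of candidate SNPs with gene-level overlap statistics,
    genomic-offset prediction of phenotypic maladaptation, and a
    synthetic-data generator that emulates a three-background,
    two-regime, two-replicate pool-seq design with seven-trait panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
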
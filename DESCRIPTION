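Package: aidscape
Title: Tracking and Testing AID-Related Somatic Mutations Across Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects canonical activation-induced cytidine deaminase (c-AID)
    mutations (C>T/G at WRCY tetranucleotide motifs and their reverse-complement
    RGYW sites) in somatic SNV tables, builds per-sample 768-channel
    tetranucleotide substitution matrices and motif-enrichment statistics, and
    tests the observed c-AID excess against a context-preserving mutation-
    shuffling null model. Includes cancer cell fraction estimation with exact
    binomial intervals and clonal/subclonal calling, genomic-distribution
    analyses (TAD domain loads, TSS-oriented profiles, R-loop overlap tests,
    inter-mutation distances, expression-mutation correlation), gene- and
    residue-level enrichment testing of AID composite mutations with a
    negative-binomial covariate model, immunogenic clonal neoepitope
    classification, and a fully seeded synthetic-cohort generator with planted
    mutational processes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
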
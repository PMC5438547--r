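Package: tstvreg
Title: Transition and Transversion Effects on Regulatory DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-arm analysis pipeline for quantifying whether transversions
    perturb regulatory DNA more than transitions. Provides pentamer-lookup DNA
    shape prediction and a random-sequence mutation-effect experiment (minor
    groove width, propeller twist, roll, helical twist); exhaustive
    single-nucleotide mutation scoring of transcription-factor binding motifs
    via log-odds position-specific scoring matrices with per-position
    information content; allele-specific binding enrichment testing with a
    two-proportion Z-test; and Ts/Tv multiple-regression analysis of reporter
    assay haplotype effects and saturation-mutagenesis enhancer data. Ships
    seeded synthetic-data generators with planted effect structure so every
    stage is testable without external downloads.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    broom,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
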
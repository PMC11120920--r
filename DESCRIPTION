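Package: founderpanel
Title: Founder-Mutation Amplicon Panels: Design, Simulation, Calibration and Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for cost-effective deep-sequencing panels that screen
    founder mutations by multiplex amplicon sequencing. Designs
    multiplex-compatible primer pairs around target mutations under
    placement, melting-temperature and cross-dimer constraints; audits
    primer footprints for known polymorphisms that cause allele dropout;
    simulates barcoded amplicon runs including primer-site-polymorphism
    dropout; calibrates per-amplicon primer concentrations to equalize
    coverage; calls genotypes from read pileups under depth and
    allele-fraction rules; and classifies cases into diagnostic-yield
    categories with cohort-level accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
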
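Package: qkatr
Title: Copy-Number Typing of KIR Genes from Multiplex qPCR (qKAT)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for quantitative KIR semi-automated typing
    (qKAT), a ten-reaction multiplex real-time PCR assay that types copy
    number at all loci of the killer-cell immunoglobulin-like receptor (KIR)
    cluster against the fixed-copy reference gene STAT6. Provides the
    published assay panel as validated data, quantification-cycle (Cq)
    extraction from amplification curves by the second-derivative-maximum
    and fit-points methods, relative quantification of integer copy number
    by the delta-delta-Cq method with calibrator-sample or
    most-frequent-copy-number calibration, linkage-disequilibrium
    consistency checks for European cohorts, gene-content haplotype-pair
    imputation against a reference haplotype table, plate-export parsing
    and splitting, and a synthetic qPCR cohort generator for validation.
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
    purrr,
    readr,
    rlang,
    minpack.lm,
    signal,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
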
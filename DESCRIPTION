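Package: mlpacnv
Title: Copy-Number Calling and Ligation-Site Indel Genotyping from MLPA Dosage Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of gene copy-number variation measured by multiplex
    ligation-dependent probe amplification (MLPA), built around the FCGR3B
    promoter assay. Converts raw peak heights into median-anchored dosage
    ratios, calls integer copy number with a BIC-selected one-dimensional
    Gaussian mixture, estimates copy number from qPCR Ct values by the
    delta-delta Ct method, models ligation-probe allele dropout caused by
    variants at the ligation junction, combines a total-copy probe with a
    wild-type-only probe into per-copy indel genotypes, and provides
    case-control association statistics (odds ratios with Woolf intervals,
    Pearson and Cochran-Mantel-Haenszel chi-square tests). A synthetic-cohort
    simulator generates peak tables, Ct tables and per-copy truth so every
    stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
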
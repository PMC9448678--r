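Package: screenforge
Title: Pooled CRISPR Screen Hit Calling and CROP-seq State Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistics and simulators for pooled CRISPRi/CRISPRa screens and
    CROP-seq single-cell perturbation experiments. Implements sgRNA-level
    phenotype scores from count tables, an empirical null built from
    negative-control quasi-genes, Mann-Whitney gene-level significance,
    standardized phenotype scores, Gene Scores, and empirical-FDR hit calling.
    For the single-cell arm it provides sgRNA singlet assignment from UMI
    matrices, knockdown-cell selection, per-target differential expression,
    cluster-occupancy enrichment relative to non-targeting controls, and
    Fisher's exact tests on cell-state proportions. Ships generative
    simulators for survival screens, FACS bin-sorting screens and CROP-seq
    experiments with known ground truth, so every stage can be exercised and
    power-tested without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
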
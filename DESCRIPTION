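Package: refstab
Title: Reference Gene Selection and Expression Stability for qRT-PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting and validating qRT-PCR reference genes in
    multi-tissue panels. Screens transcriptome abundance (TPM) tables for
    low-variability candidates by coefficient of variation within tissue
    groups; estimates primer amplification efficiency from dilution series;
    ranks candidate reference genes with four quantification-cycle based
    stability algorithms (geNorm, NormFinder, BestKeeper and the comparative
    delta-Ct method) and aggregates them into a comprehensive geometric-mean
    ranking; and computes efficiency-corrected relative expression ratios
    against a calibrator tissue with ANOVA and Bonferroni-adjusted pairwise
    comparisons. A synthetic-data generator produces TPM matrices, Ct
    matrices with planted stable and unstable genes, and dilution series
    with known ground truth, so the whole pipeline is testable end to end.
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
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
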
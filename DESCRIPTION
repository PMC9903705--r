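Package: mptsc
Title: Clonal Substructure Analysis for Multi-Patient Targeted Single-Cell DNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of multi-patient targeted (MPT) single-cell DNA
    amplicon sequencing: quality filtering of single-cell genotype matrices,
    clonal clustering of cells, amplicon read-depth copy-number ratio
    estimation, depth-based doublet identification, neighbor-joining
    mutational lineage trees with branch-level mutation and copy-number
    event annotation, panel design feasibility filters, and coverage
    uniformity / allelic dropout / bulk-concordance benchmarking. Includes
    a synthetic-data generator producing amplicon count and genotype
    matrices with clonal substructure, allelic dropout, doublets and
    per-amplicon efficiency variation, together with matched ground truth
    and pseudo-bulk references.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
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
    uwot,
    vcfR,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
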
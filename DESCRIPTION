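Package: immunopep
Title: Comparative Analysis of HLA Class I Immunopeptidomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing the peptide repertoires of closely related
    HLA class I allotypes from immunoaffinity-purification mass-spectrometry
    identifications. Implements confidence and contaminant filtering of
    peptide-identification tables, length and position-frequency motif
    summaries, proteome-background enrichment statistics, inter-position
    statistical coupling (covariation) matrices, physicochemical PCA with
    k-means/silhouette clustering, repertoire overlap under a
    confidence-rescue rule, validation and beta-2-microglobulin-normalised
    relative quantification of multiple-reaction-monitoring (MRM) data, and
    Boltzmann-sigmoid thermal-melt (Tm) analysis with delta-Tm
    classification. A seeded synthetic-data module generates peptide tables,
    MRM transition tables and melt curves with known ground truth so that
    every stage of the pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    minpack.lm,
    cluster,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
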
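Package: sevmir
Title: Serum Small Extracellular Vesicle miRNA Biomarker Analysis for the
    Mouse Tibia Fracture Model of CRPS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible reimplementation of a serum small
    extracellular vesicle (sEV) microRNA biomarker analysis for the mouse
    tibia fracture model (TFM) of complex regional pain syndrome (CRPS).
    Provides sample-level quality control for nuclease-protection miRNA
    panels (total reads, positive-control spike fraction, housekeeping
    coefficient of variation), TPM normalization, group-wise
    presence-absence partitioning, housekeeping-relative fold change with a
    permutation t-test for differential expression, multiplex cytokine
    panel statistics (LLOQ imputation, protein normalization, Welch t with
    Benjamini-Hochberg adjustment), cross-cohort miRNA signature overlap
    with name harmonization, and miRNA-target GO over-representation with
    term-similarity outputs.  A synthetic data module generates panel
    counts, cytokine tables, and annotation resources with planted ground
    truth so the whole pipeline can be exercised and validated without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    ape,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
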
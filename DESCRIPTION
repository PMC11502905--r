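Package: lrperm
Title: Ligand-Receptor Cross-Talk Screening for Plate-Based Single-Cell
    RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality control, normalization and cell-cell communication
    inference for plate-based (384-well, UMI) single-cell RNA-seq count
    data. Implements median-absolute-deviation doublet exclusion, a UMI
    floor and a mitochondrial-fraction ceiling for cell quality control;
    library-size log-normalization and group-mean expression summaries;
    a ligand-receptor interaction score between two cell populations with
    an empirical permutation null obtained by shuffling cell-type and
    time-point labels; Wilcoxon rank-sum marker detection with Bonferroni
    correction and hypergeometric signature-overlap tabulation; and a
    seeded negative-binomial simulator of sorted-plate experiments with
    planted interactions, markers, doublets and dying cells for
    calibration and recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
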
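Package: premcnv
Title: Pre-Malignant Cell Identification from Single-Cell Expression CNV Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies pre-malignant versus malignant epithelial cells in
    single-cell RNA-seq of tumor and adjacent (paracarcinoma) tissue. Implements
    adaptive per-sample quality control (mean + 2.58 SD upper thresholds with
    fixed floors), reference-anchored copy-number-variation (CNV) profile
    inference by moving-average smoothing of centered log-expression along
    genomic gene order, a spike-in dendrogram test for normal epithelial cells,
    Euclidean-distance banding against a fibroblast median baseline, gene-set
    (stemness) module scoring, and marker-rule epithelial subtyping. Ships a
    negative-binomial synthetic-data generator with implanted CNV segments so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
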
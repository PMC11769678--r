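Package: structf
Title: Structure-Aware Transcription Factor Prediction from Protein Secondary Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a protein is a transcription factor (TF) from its
    amino-acid sequence jointly with its per-residue secondary structure. Each
    protein is one-hot encoded as a padded 1000 x 63 matrix over the 21-letter
    residue alphabet crossed with three secondary-structure groups (alpha-helix,
    beta-sheet, coil-turn) collapsed from the eight DSSP categories, and
    classified by a convolutional network with three parallel subnetworks. The
    package covers the full study pipeline: parsing AlphaFold-style PDB files
    (per-residue pLDDT in the B-factor field) and classic DSSP output,
    eligibility and structure-reliability filtering, GO-term based TF
    annotation, redundancy-aware dataset curation from sequence-cluster tables
    with class-ratio sampling and stratified cross-validation splits, seeded
    model training and evaluation (AU-ROC, AU-PRC, Matthews correlation
    coefficient, paired Wilcoxon comparisons), integrated-gradients attribution
    with DNA-binding-domain aggregation, and a synthetic-cohort generator that
    plants a secondary-structure-dependent motif for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp,
    bio3d,
    Biostrings
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
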
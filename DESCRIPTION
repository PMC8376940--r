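Package: ppirof
Title: Sequence-Based Protein-Protein Interaction Prediction with
    Orthogonal Locality Preserving Projections and Rotation Forest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interactions from sequence alone.
    Protein sequences are represented by PSI-BLAST position-specific
    scoring matrices (PSSMs), summarised as fixed-length evolutionary
    descriptors, embedded in a low-dimensional space by Orthogonal
    Locality Preserving Projections (OLPP, a graph-Laplacian manifold
    embedding with mutually orthogonal basis vectors), and protein pairs
    are classified by a Rotation Forest ensemble of CART trees trained in
    randomly rotated feature subspaces. Includes the full evaluation
    protocol (accuracy, precision, sensitivity, Matthews correlation
    coefficient, ROC/AUC, stratified five-fold cross-validation, K-by-L
    grid search), a synthetic benchmark generator with a controllable
    class signal, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    rpart,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
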
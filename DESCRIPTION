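Package: gtmcc
Title: Graph-Regularized Transductive Matrix Co-Completion for Drug
    Side-Effect and Target Prediction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint prediction of drug side effects and imputation of missing
    drug-target associations by low-rank co-completion of the concatenated
    binary association matrix Z = [Y, X].  Observed-positive entries and
    unobserved entries receive asymmetric squared-error weights
    (positive-unlabelled learning), the drug latent factors are smoothed over
    a k-nearest-neighbour chemical-similarity graph through its normalized
    Laplacian, and the factors are fitted by proximal alternating linearized
    minimization with Lipschitz step sizes.  Includes Tanimoto
    fingerprint similarities, local/global/target cross-validation protocols
    with multi-label ranking metrics (AUC, average precision, label-ranking
    average precision, coverage error, ranking loss), a seeded low-rank
    synthetic-data generator with positive-unlabelled masking, readers and
    writers for pair-list, fingerprint and similarity-matrix files, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
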
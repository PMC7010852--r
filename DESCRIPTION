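Package: puimc
Title: Disease-Gene Prioritization by PU Inductive Matrix Completion
    with Heterogeneous Feature Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prioritizes candidate disease genes by completing a sparse
    gene-disease association matrix with a positive-unlabeled (PU) biased
    inductive matrix completion model. Gene and disease features are learned
    from heterogeneous sources: random walk with restart turns similarity
    networks into diffusion states, a log-transform plus truncated SVD
    (diffusion component analysis) compresses them into node and context
    embeddings, and a denoising autoencoder compresses dense noisy feature
    tables. Includes the recall, precision and mean-percentile-ranking
    evaluation protocols (global three-fold cross-validation, new-gene and
    new-disease hold-outs) and a synthetic fixture generator that plants
    low-rank bilinear associations for end-to-end recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
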
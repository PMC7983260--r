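Package: vemlda
Title: Variational EM Graph Autoencoders for lncRNA-Disease Association
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts associations between long non-coding RNAs and
    diseases from a partially observed binary association matrix and
    per-node features. Two graph autoencoders are trained alternately by
    a variational EM scheme: a variational autoencoder infers latent node
    representations from features on a mutual k-nearest-neighbour graph,
    and a plain autoencoder propagates association labels on the same
    graph; the two are coupled through a manifold loss on the latent
    representations and a co-training loss linking the lncRNA and
    disease spaces through the labels. Includes k-mer skip-gram sequence
    embeddings, masked cross-validation over known associations, metrics
    for heavily imbalanced evaluation (AUPR, Matthews correlation,
    fixed-specificity operating points, top-k true-positive counts), and
    a synthetic low-rank benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
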
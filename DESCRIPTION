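Package: ennrl
Title: Completing Sparse Disconnected Protein Interaction Networks with an
    Evolution Neural Network and Regularized Laplacian Kernel
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Link prediction for sparse, disconnected protein-protein
    interaction (PPI) networks.  A five-layer zero-input neural network with
    an autoencoder-like bottleneck is trained on the rows of a partial
    adjacency matrix to produce an "evolved" interaction matrix; a
    regularized Laplacian diffusion kernel over the resulting transition
    matrix then scores every protein pair, including pairs that lie in
    different connected components of the training network.  Also provides
    heterogeneous feature-kernel construction and nonnegative least-squares
    fusion-weight fitting against the learned transition matrix, golden
    standard edge splitting, a duplication-divergence synthetic network
    generator, ROC/AUC evaluation with component-reconnection analysis, and
    a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
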
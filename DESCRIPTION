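Package: conndecode
Title: Task-State Decoding from Functional Connectomes with Spectral Graph
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted functional brain graphs from parcellated fMRI
    time series (Pearson correlation, Fisher z transform, proportional or
    absolute thresholding), attaches per-node statistical time-series
    features and topological node embeddings (Node2Vec, Walklets, NetMF,
    RandNE, all implemented from scratch), classifies task state with a
    three-layer spectral graph convolutional network trained by Adam with
    batch normalization, dropout and global mean pooling, and evaluates the
    classifier with stratified cross-validation, a full multiclass metric
    suite including the Gorodkin Matthews correlation coefficient, an
    L2-regularized multinomial logistic baseline, and a repeated-run
    group-difference test (Shapiro-Wilk followed by Welch's t-test). A
    synthetic multi-subject generator with planted block-community
    connectivity makes the whole pipeline runnable without any imaging data.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    mclust,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
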
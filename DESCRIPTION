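Package: nmphtools
Title: Correlation-Targeted Stimulus Synthesis and Nonmonotonic
    Representational-Change Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying learning-driven representational change with
    model-based stimuli. One half synthesizes pairs of images whose feature
    correlations at chosen layers of a differentiable feature extractor are
    driven to prescribed targets (activation maximization, correlation
    tuning, Laplacian-pyramid gradient regularization, multi-scale volleys),
    together with a deterministic toy convolutional extractor so the whole
    algorithm runs without pretrained weights. The other half implements a
    representational similarity analysis pipeline for temporal statistical
    learning experiments: templating and paired-sequence design generation,
    double-gamma GLM pattern estimation, pairmate pattern similarity,
    model-brain correspondence, pre-to-post representational change, a
    theory-constrained cubic (U-shaped) model of the nonmonotonic plasticity
    hypothesis with leave-one-participant-out cross-validation, participant
    bootstrap confidence intervals, and pairmate re-shuffling permutation
    nulls. A synthetic-data generator with planted ground truth supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
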
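Package: ginger
Title: Instance-Based Learning Agents with Generative-Model Memories and Actions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Implements the GINGER family of cognitive models of experiential
    decision making: Instance-Based Learning (IBL) agents built on ACT-R style
    activation, soft-max retrieval and blended values, extended with
    generative-model memories (beta-VAE latent posteriors compared by
    KL-divergence, text embeddings compared by cosine similarity) and
    generative-model actions (utility-prediction networks trained to match IBL
    blended values). Ships seeded simulators for a nine-feature contextual
    bandit, a three-phase transfer-of-learning task and a synthetic phishing
    identification task, together with model-versus-behavior statistics
    (learning curves, mean residual sum of squares, BIC, transfer metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
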
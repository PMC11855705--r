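Package: cdaae
Title: CircRNA-Drug Association Prediction with Adversarial Autoencoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts associations between circular RNAs and drug sensitivity
    from fused similarity representations. CircRNA host-gene sequences are
    compared by normalized Levenshtein distance, drugs by Tanimoto similarity
    of topological fingerprints, and both are fused with Gaussian
    interaction-profile kernels derived from the known association matrix.
    Per-pair similarity features are refined by a multi-scale 1-D
    convolutional network and an adversarial autoencoder whose latent code is
    pushed towards a standard-normal prior, then scored by a deep classifier.
    Includes balanced negative sampling, k-fold cross-validation and blind
    test protocols, ablation switches, and a synthetic data generator with
    planted block association structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    ChemmineR,
    ChemmineOB
Config/testthat/edition: 3
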
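Package: mregle
Title: Multimodal Waveform Embeddings for Genetic Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Joint (early-fusion) low-dimensional representation learning of
    multimodal physiological waveforms (such as 12-lead ECG median complexes
    and PPG median beats) with a variational autoencoder, followed by PCA
    orthogonalization of the embeddings, covariate-adjusted per-coordinate
    association testing, a summed chi-squared combined statistic referred to
    a chi-squared distribution with as many degrees of freedom as retained
    coordinates, greedy LD clumping and locus construction, and elastic-net
    genetic risk scores.  Includes a synthetic multimodal waveform and
    genotype generator, calibration and power simulation studies comparing
    the combined statistic with MANOVA, and an end-to-end synthetic
    benchmark, so the whole pipeline is testable without biobank access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
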
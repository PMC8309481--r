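Package: gencs
Title: Task-Driven Image Compressed Sensing with Learned Sampling and
    Generative Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compressed sensing of structured images at very low sampling
    rates using a fully learnable pipeline: a linear learnable Sampler whose
    weights form the measurement matrix, a Solver network mapping
    measurements to a latent Gaussian distribution, and a generative
    Rebuilder trained with combined variational and adversarial losses.
    Images are reconstructed from measurements by initialising the latent
    code from the Solver and iteratively minimising the measurement
    consistency loss over the latent space with the networks frozen.
    Includes seeded synthetic generators for rosette-like plant images and
    face-like images, an analytically solvable linear-decoder world used as
    a verification oracle, empirical restricted-eigenvalue diagnostics for
    measurement matrices, and PSNR/SSIM image quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
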
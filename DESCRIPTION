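Package: emtomo
Title: Synthetic Data and Deep-Learning Reconstruction for 2D Electromagnetic Medical Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates randomized multi-geometry dielectric phantoms with
    tissue-like permittivity and conductivity, simulates multistatic scattered
    time-domain signals with a 2D transverse-magnetic finite-difference
    time-domain (FDTD) solver terminated by a convolutional perfectly matched
    layer, preprocesses the raw 16x16x5000 signal tensors into normalized
    256x256 network inputs, trains an encoder-decoder (U-net style) network to
    reconstruct permittivity maps, and evaluates reconstructions with SSIM,
    NRMSE and PSNR. Includes a seeded, versioned on-disk case store and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
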
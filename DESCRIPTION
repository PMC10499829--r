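Package: descatter
Title: Simulation and Learned De-Scattering for Patterned-Excitation
    Multiphoton Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A physics-based forward simulator of patterned-excitation
    temporal-focusing two-photon microscopy through scattering tissue and a
    learned inverse model that de-scatters images from a small number of
    patterned measurements. Includes Monte Carlo simulation of per-depth
    scattering point spread functions (Henyey-Greenstein phase function),
    a stochastic EMCCD detection model with the electron-multiplication
    cascade and its excess-noise statistics, synthetic bead and vessel
    phantom generators, paired-dataset assembly, a convolutional
    encoder-decoder network with concurrent spatial and channel
    squeeze-and-excitation attention trained by backpropagation, and
    SSIM/PSNR/MSE evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp
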
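Package: mugen
Title: CT-Free Attenuation-Map Synthesis for Quantitative Kidney SPECT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale toolkit for generating synthetic attenuation maps
    (mu-maps, cm^-1 at 140 keV) from dual-energy-window Tc-99m DTPA kidney
    SPECT volumes without CT. Provides a digital kidney phantom and
    attenuated-emission SPECT simulator, maximum and logarithmic-maximum
    input normalization, a modified 3D U-Net generator (instance
    normalization, nearest-neighbor interpolation up-sampling) trained with
    an L1 plus gradient-difference loss family, voxel-wise evaluation
    metrics (R squared, MSE, percent NMAE) with a checkerboard-artifact
    index, first-order Chang attenuation correction, and renal
    quantification (percent uptake, GFR, effective dose and dose-reduction
    arithmetic).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
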
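Package: qdenoise
Title: Denoising and Quantitation of Quantum-Dot Fluorescence Images from
    Porous-Silicon Biosensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Removal of multiplicative gamma (speckle-like) noise from
    quantum-dot fluorescence micrographs of porous-silicon array biosensors,
    and the downstream gray-value quantitation that turns average gray levels
    into analyte concentrations.  Implements gray-value compression (GVC)
    preprocessing against a non-local-means reference, cosine-distance
    nonlocal anisotropic diffusion (CNLAD) with a type-2 fuzzy diffusion
    gate, coefficient-of-variation noise-level estimation from homogeneous
    regions, a multiplicative-noise simulator and ten-class noise dataset
    generator, image quality metrics (AGL, RMSE, SSIM), and calibration-curve
    fitting with a 3-sigma/slope detection limit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    nnet,
    png,
    tiff,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
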
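Package: sadhm
Title: Synthetic-Aperture Digital Holographic Microscopy: Simulation,
    Aberration Estimation and Fourier-Domain Aperture Synthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scalar-diffraction simulator and reconstruction toolkit for a
    synthetic-aperture digital holographic microscope (SA-DHM). Simulates
    angularly scanned plane-wave illuminations carrying Zernike wavefront
    aberrations through a 4-f imaging system with a numerical-aperture mask,
    records parallel 4-step phase-shifted holograms and recovers the complex
    object field, estimates the ten lowest Zernike coefficients of the
    illumination beam from three-channel diffraction-intensity images with a
    compact residual convolutional network (including dark-field
    illuminations whose wavefront never reaches the camera directly),
    compensates the estimated aberrations, stitches the spectral tiles in
    the Fourier domain with piston-phase matching, and quantifies the
    resolution gain with bar-target modulation transfer function (MTF)
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
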
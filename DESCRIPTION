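Package: osteoraman
Title: Polarized Raman Analysis of Apatite Orientation in Osteonal Bone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative polarized Raman microspectroscopy of
    cortical bone at the osteon scale. Deconvolutes the phosphate nu1
    stretching region (~960 1/cm) into Lorentzian-Gaussian (pseudo-Voigt)
    sub-bands and extracts per-position intensity, band position and FWHM
    layers from line scans and hyperspectral maps; forward-models and fits
    polarized intensity versus in-plane rotation for an orientation-
    distributed population of hexagonal apatite crystallites, returning
    Euler angles, maximum-entropy ODF multipliers and Hermans orientation
    parameters; estimates the in-plane Gaussian probe response function
    from cavity-edge line scans and provides the corresponding convolution
    operator; and fits a twisted/oscillating plywood mixture model to
    probe-convolved out-of-plane angle profiles across osteonal lamellae.
    A synthetic-scene generator produces every input with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
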
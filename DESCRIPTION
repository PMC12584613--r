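Package: ramanIS
Title: Internal-Standard Raman Quantification of Sulfate in Solid Media
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative confocal Raman spectroscopy of sulfate at the
    gas-solid interface of solid culture media, using the nitrogen N2
    stretching band (2332 1/cm) at fixed headspace pressure as an internal
    standard. Provides a full processing chain: cosmic-ray despiking,
    asymmetric-least-squares and polynomial baseline correction, silicon
    wavenumber calibration, replicate averaging, single- and multi-Gaussian
    peak fitting (including deconvolution of the carotenoid band overlapping
    the sulfate S-O stretch at 980 1/cm), peak-area ratio computation, linear
    calibration fitting with inverse concentration prediction, univariate
    band-integration imaging of spectral maps (S8 at 470 1/cm, carotenoids at
    1523 1/cm), and light/dark time-course quantification. Includes a
    deterministic synthetic-spectrum generator with known ground truth for
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
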
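Package: foragenirs
Title: Forage Nutritive Value Calibration from Near-Infrared Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric calibration of forage nutritive value (neutral
    detergent fiber, digestibility, lignin, crude protein) from
    near-infrared reflectance spectra. Implements NIPALS partial least
    squares regression with explained-X-variance latent-variable
    selection, a spectral preprocessing grid (standard normal variate
    and detrend, Savitzky-Golay smoothing and derivatives), venetian
    blinds cross-validation, harvest-date validation splits, and the
    full suite of NIRS error statistics (SEC, SECV, RMSEP, SEP, bias,
    slope, R2 and the laboratory-error ceiling R2MAX). Includes a
    two-instrument simulator emulating a 2 nm benchtop scanning
    monochromator and a 16 nm handheld Fourier-transform spectrometer,
    so instrument-comparison experiments can be run without
    proprietary spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    Matrix,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
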
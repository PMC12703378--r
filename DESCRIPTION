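Package: vinispec
Title: Vis-NIR Chemometric Calibration for Table Grape Quality Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A config-driven chemometric calibration workflow for visible/
    near-infrared (Vis-NIR) reflectance spectra of table grapes during
    storage. Implements spectral pretreatments (first derivative,
    Savitzky-Golay smoothing, standard normal variate, multiplicative
    scatter correction), rank-based calibration/prediction partitioning,
    characteristic-wavelength selection (successive projections algorithm,
    uninformative variable elimination, competitive adaptive reweighted
    sampling), calibration models (NIPALS partial least squares, RBF
    support vector regression, extreme learning machine), and Rc/Rp/RMSE/
    RPD model evaluation over a preprocessing x selector x model grid.
    Ships a synthetic spectra generator that plants known analyte
    absorption bands so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
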
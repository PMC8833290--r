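Package: cbctqa
Title: Image-Quality and Geometric-Stability QA for Cone-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative quality-assurance metrics for cone-beam computed
    tomography (CBCT) scanners evaluated with modular QA phantoms:
    CT-number accuracy and linearity, edge-versus-center uniformity,
    contrast-to-noise ratio, the difference-image ROI-ensemble 2D noise
    power spectrum with radial reduction and integrated noise magnitude,
    slanted-edge spatial resolution (oversampled edge-spread function,
    Fermi-function characterization, modulation transfer function and
    limiting frequency), the weighted cone-beam dose index from pencil
    chamber dose-length products, and reproducibility statistics for
    gantry-angle-dependent geometric (flexmap) calibrations. A synthetic
    phantom and calibration-data generator with known ground truth makes
    every metric verifiable by parameter recovery without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
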
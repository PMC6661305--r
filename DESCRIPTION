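Package: thyroscint
Title: Planar Scintigraphy Thyroid Uptake Quantification (TcTU, UR, CUR)
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies technetium-99m pertechnetate thyroid uptake from
    planar gamma-camera count images. Computes the quantitative uptake
    percentage (TcTU) from syringe dose-calibrator assays, a camera
    calibration factor, decay correction and injection-site leakage
    subtraction; the semiquantitative thyroid-to-background uptake ratio
    (UR); and the area-standardized corrected uptake ratio (CUR).
    Establishes mean +/- 1.96 SD reference ranges, assigns three-class
    uptake labels, tabulates concordance between semiquantitative and
    quantitative classes with likelihood-ratio and Pearson chi-square
    tests, and fits weighted least-squares regressions with standardized
    coefficients. Includes a synthetic planar-phantom generator (Poisson
    counting noise, elliptical-lobe gland geometry, cohort emulation) so
    the whole pipeline is testable without patient data, plus a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
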
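Package: pfasq
Title: High-Resolution Accurate-Mass PFAS Quantitation and EPA 537.1-Style
    Method Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Targeted exact-mass LC-MS quantitation of per- and polyfluoroalkyl
    substances (PFAS) against stable-isotope internal standards, with the
    replicate-calibration validation statistics recommended by EPA Method
    537.1: half-range prediction intervals (HR_PIR), minimum reporting limits
    (MRL), detection limits (DL), and initial demonstrations of precision and
    accuracy (IDP/IDA). Includes exact-mass and isotope-pattern chemistry for
    a packaged 45-analyte / 23-internal-standard PFAS registry, extracted-ion
    chromatogram (XIC) extraction and peak integration from centroided scan
    streams, spectral dot-product (dotp) and isotope-envelope (idotp)
    identity scoring, internal-standard-ratio calibration with weighted least
    squares, surrogate-internal-standard screening by fluorine count, and a
    synthetic-data generator that emulates replicate calibration studies and
    inclusion-list acquisition for end-to-end testing without an instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
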
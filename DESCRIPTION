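Package: dualECG
Title: Dual-Device Validation of Unobtrusive ECG Recordings
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to validate an experimental "off-the-person"
    electrocardiography channel against a simultaneously recorded
    gold-standard reference: plain-text acquisition file input/output,
    optical (LED/luminosity) synchronization of two independent streams,
    zero-phase FIR band-pass conditioning, Hamilton R-peak detection,
    matched-beat heart-rate comparison (QRS count ratio, heart-rate
    difference, signal detection error), Poincare and detrended-fluctuation
    heart-rate-variability analysis, DMEAN beat-template outlier rejection,
    and beat-morphology scoring by Pearson correlation and range-normalized
    RMSE, together with a ground-truth synthetic dual-device ECG generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, signal
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
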
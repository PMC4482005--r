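Package: fallwav
Title: Wavelet-Based Fall Detection from Tri-Axial Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects falls in body-worn tri-axial accelerometer recordings by
    matching the acceleration sum vector against an adapted mother wavelet
    built from averaged peak-centered fall windows. Provides the fitting
    function fall_wavelet() with print, plot and predict methods, a
    continuous-wavelet-transform similarity score restricted to the
    scale/translation box around twice the sampling frequency, classic
    upper/lower peak value baseline features, cross-validated evaluation with
    vertically averaged ROC curves, Youden-index operating points, exact
    paired Wilcoxon signed-rank comparisons, and a seeded simulator of
    one-minute fall and activity-of-daily-living recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
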
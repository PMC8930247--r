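Package: knlmeans
Title: K-Means-Guided Non-Local Means Speckle Denoising for Ultrasound
    Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Speckle-noise reduction for 2-D grayscale ultrasound images by
    non-local means (NL-Means) patch filtering, a gradient-augmented variant
    that strengthens edge preservation, and the KNL-Means combination in
    which a K-means classification of pixels restricts the non-local search
    to candidates of the same tissue class.  Ships a synthetic kidney-like
    speckled phantom generator, a robust image noise standard deviation
    estimator used to set the filter bandwidth, PSNR/MSE quality metrics, a
    multi-method evaluation harness, the renal Doppler resistive index
    RI = (PSV - EDV)/PSV, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
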
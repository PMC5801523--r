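Package: swaybam
Title: Accelerometer-Based Standing Balance Analysis for Head- and
    Waist-Mounted Wearables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying standing balance from body-worn
    accelerometers following the six-condition balance accelerometer
    measure (BAM) protocol. Reads time-stamped three-axis accelerometer
    trial files, applies the standard trim and low-pass Butterworth
    preprocessing, computes anterior-posterior and total normalized path
    length (NPL) sway metrics and standardized composite scores, and
    estimates the validation statistics used for inter-device comparison
    and test-retest reliability: Spearman rank correlation, Fisher-z
    correlation comparison, two-way random-effects single-measure
    intraclass correlation ICC(2,1) with confidence intervals,
    Kruskal-Wallis condition contrasts, and Anderson-Darling normality
    checks. Includes a synthetic two-device balance study generator with
    known variance components for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    nortest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
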
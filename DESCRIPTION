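Package: sonosym
Title: Symmetry-Aware Two-Stage Lesion Detection for Bilateral B-Mode Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects focal hypoechoic muscle-strain lesions in bilateral B-mode
    ultrasound image pairs with a two-stage cascade: a lightweight anchor-based
    detector proposes scored candidate boxes, and a Siamese similarity network
    verifies mid-confidence candidates against their contralateral reference
    regions, localized by mirroring plus Histogram-of-Oriented-Gradients (HOG)
    matching. Includes a bilateral speckle-phantom simulator with known lesion
    ground truth, patch-pair mining for filter training, and a full evaluation
    protocol (IoU matching, precision/recall/F-beta, average precision,
    patient-level cross-validation splits, stratified bootstrap confidence
    intervals, inter-reader kappa statistics, and operating-point sweeps).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
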
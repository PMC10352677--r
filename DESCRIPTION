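Package: hyperleaf
Title: Hyperspectral Reflectance and Fluorescence Pipeline for Plant
    Stress Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and analysis pipeline for line-scan (pushbroom)
    hyperspectral plant-health monitoring in controlled-environment crop
    production. Reads and writes band-interleaved-by-line (BIL) hypercubes
    with ENVI-style headers, performs spectral calibration and scan
    planning, spectral/spatial block averaging and flat-field reflectance
    conversion against a reference panel, correlation-driven two-band
    ratio selection with Otsu masking for plant segmentation, translation
    registration of reflectance/fluorescence image pairs, masked spectral
    feature extraction with a 3x3 average-window outlier filter, leaf-area
    time series testing, and repeated cross-validated comparison of seven
    classifier families for drought-stress detection. Includes a synthetic
    phantom-scene generator (lettuce on soil with a reference panel strip)
    so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    class,
    e1071,
    nnet,
    rpart,
    randomForest,
    pROC,
    jsonlite,
    yaml,
    png
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
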
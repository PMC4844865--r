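Package: appendixsom
Title: Automatic Appendix Extraction from Abdominal Ultrasound with
    Self-Organizing Map Quantization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A fully automatic pipeline that extracts the vermiform appendix
    from B-mode abdominal ultrasound frames and measures its diameter in
    millimetres. Stages: ends-in search contrast stretching, trapezoidal fuzzy
    binarization with an alpha-cut, 8-directional (Moore) contour tracing,
    fascia-line reconstruction by cubic-spline reconnection of detected
    segments, hexagonal-grid self-organizing-map intensity quantization of the
    sub-fascial region, and candidate filtering with second-moment ellipse
    measurement against the 6 mm appendicitis criterion. Includes a seeded
    synthetic phantom generator emulating four clinically observed
    shape-brightness appendix patterns, with ground-truth masks, so the whole
    pipeline is testable without clinical images.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
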
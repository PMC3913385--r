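Package: plaquantify
Title: Quantitative Light-Induced Fluorescence Plaque Quantification and
    Case-Control Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies dental plaque from intraoral quantitative
    light-induced fluorescence (QLF) images: disclosed-plaque coverage by
    red/green channel-ratio thresholding within polygon tooth regions of
    interest, and red-fluorescent (porphyrin) plaque as the percentage
    elevation of red fluorescence (delta-R) over a plaque-free elliptical
    reference.  Aggregates per-tooth measurements to subject level under
    reproducible exclusion rules and runs a case-control statistical
    battery (pooled t-tests, chi-squared tests, Pearson correlation,
    multiple logistic regression with Wald odds ratios).  Includes
    synthetic image and cohort generators with ground truth for offline
    benchmarking of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
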
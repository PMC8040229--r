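Package: toothct
Title: Automated Micro-CT Morphology of Single-Rooted Teeth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated segmentation and description of the internal
    morphology of single-rooted teeth from micro-CT reconstruction stacks:
    cropping to the tooth by fixed-threshold segmentation and largest-object
    bounding box, per-slice root-canal extraction (Otsu split, inversion,
    border clearing, speckle removal, hole filling), enamel-dentin-border
    detection from the LOWESS-smoothed axial brightness profile, 4-digit root
    canal configuration coding, and physiological-foramen geometry via an
    exact Euclidean distance transform. Includes a synthetic tooth-phantom
    generator with analytic ground truth so every stage is testable without
    real scans, plus a batch pipeline with quick-look overview images and a
    thin command-line front end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
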
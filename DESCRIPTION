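Package: belugadetect
Title: Object-Based Detection of Beluga Whales in Very High-Resolution
    Satellite Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated object-based image analysis (OBIA) for locating
    beluga-whale-sized bright targets in single-band very high-resolution
    panchromatic ocean imagery. Implements land masking, high-pass spatial
    filtering, gradient (EDGE) watershed segmentation with a 0-100 scale
    level, fast lambda-schedule region merging with a 0-100 merge level,
    per-segment spectral, kernel-texture and spatial attributes, threshold
    rule sets (including the eleven published candidate algorithms),
    detection-object grouping, and ground-truth matching with the false
    negative rate, false positive rate and automated count deviation
    accuracy metrics. Ships a synthetic ocean-scene generator with known
    whale ground truth so the full pipeline is testable without licensed
    imagery, plus single-band GeoTIFF and GeoJSON input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    igraph
Config/testthat/edition: 3
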
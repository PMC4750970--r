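Package: grainhash
Title: Hash-Based Pixel Classification and Species-Ratio Reconstruction for
    Pollen Slide Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-pass visual recognition for brightfield microscopy slides of
    pollen grains. A first pass segments pollen pixels from the slide
    background with a locality-sensitive-hashing histogram classifier built
    from quantized pixel-grid features ("pollen spotting"). A second pass
    classifies the spotted pollen pixels into two species, either by
    distance-threshold rules over vertical pixel-line profiles (reconstructing
    per-slide species mixture ratios) or by a confidence-gated window
    classifier that aggregates pixel votes to grain-level and slide-level
    calls. Includes single-dimension-at-a-time coordinate descent and seeded
    random search over classifier parameters, learning-curve utilities, a
    synthetic slide simulator with known ground truth for end-to-end
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
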
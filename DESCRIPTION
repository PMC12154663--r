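Package: floracline
Title: Flower-Color Phenotyping and Geographic Divergence Analysis from
    Community-Science Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for extracting flower-color phenotypes from georeferenced
    photographs and testing for geographic color divergence. Images are
    reduced to a single robust CIELAB color via the geometric median of
    segmented flower pixels; observation colors are aggregated on an
    equal-area km grid and compared between regions with Hotelling's T-squared
    tests, including a sliding longitudinal breakpoint scan and k-means
    cluster profiling to localize a color cline without a predefined boundary.
    Validation utilities cover mask serialization and mean
    intersection-over-union, hue-window outlier screening, inter-rater
    agreement (Cohen's kappa), and lighting-bias factorial ANOVA/MANOVA.
    A synthetic-data generator produces cohorts of observations, rendered
    flower images, ground-truth masks, and rater annotations with planted
    regional effects for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    farver,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
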
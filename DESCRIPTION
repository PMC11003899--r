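Package: glomorph
Title: Glomerular Morphometry from Kidney Section Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end pipeline for glomerular morphometry on
    hematoxylin-eosin stained kidney sections: segmentation of section
    images into background, cortex and medulla, detection and size
    filtering of glomeruli, per-slide and per-individual morphometry
    (glomerular density, cross-sectional area, perimeter, Weibel-Gomez
    volume, volumetric glomerular density), validation of detections
    against reference counts, and cohort statistics with normality-gated
    two-group tests, median splits, correlations and a univariate-to-
    adjusted regression strategy. Includes a synthetic slide and cohort
    generator with known ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
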
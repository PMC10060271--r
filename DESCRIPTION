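Package: organoidscreen
Title: Label-Free Organoid Screening: Simulation, Segmentation, Kinetics and Drug-Response Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for image-based drug screening of
    patient-derived organoids in microplate wells. Provides a synthetic
    plate-image generator with known per-organoid ground truth (solid and
    cystic morphologies, exponential growth with density-dependent slowdown,
    organoid fusion, dose-dependent death-marker accumulation, imaging
    artifacts), label-free brightfield segmentation (a deterministic
    classical chain and a small trainable encoder-decoder semantic
    segmentation network trained against fluorescence-derived ground truth),
    overlap-based object tracking with fusion events, per-well kinetic
    metric tables with intra-well normalization, and a drug-response
    analytics layer: four-parameter logistic IC50/EC50 fitting, the extra
    sum-of-squares F test for comparing log IC50 values, the Z-factor screen
    quality score, growth-rate (GR) and normalized drug response (NDR)
    metrics, and cytostatic versus cytotoxic classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
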
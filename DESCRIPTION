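Package: radqc
Title: Automated Quality Control for Chest Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-stage quality-control pipeline for chest radiographs:
    pixel-intensity standardization via value-of-interest windowing,
    geometric standardization (padding/collimation cropping, 90-degree
    rotation correction, aspect-ratio screening), burned-in annotation
    detection and inpainting, and projection classification with header
    consistency checking and no-reference quality scoring. Includes
    dataset-curation rules (one image per patient, age-range midpoints,
    missing-field exclusion, stratified 64/16/20 partitioning), bootstrap
    evaluation metrics, occlusion-based saliency maps, a shortcut-learning
    experiment quantifying reliance on burned-in text, and a synthetic
    chest-phantom generator with complete ground truth for end-to-end
    verification. Reads and writes uncompressed little-endian DICOM and
    PNG with JSON metadata sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png,
    glmnet,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
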
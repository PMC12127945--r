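# radqc — automated quality control for chest radiographs

`radqc` is an R package implementing a deterministic, rule-based quality-control
pipeline for chest radiographs, together with a fully synthetic phantom
generator that provides exact ground truth for verifying every stage.

## Why

Radiograph collections gathered across sites and years are messy in ways that
hurt machine-learning models twice over:

- **Distribution shift.** Manufacturer-specific gamma curves, offsets, and
  display LUTs make identical anatomy look different across scanners.
- **Shortcut learning.** Burned-in text (projection labels, laterality
  markers) is often correlated with the prediction target, so a model can
  score well by reading the text instead of the anatomy — and then collapse
  when the text changes or disappears at deployment.

`radqc` addresses both: it standardizes intensity via value-of-interest
windowing, standardizes geometry (padding/collimation cropping, 90° rotation
correction, aspect-ratio screening), detects and inpaints burned-in
annotations, cross-checks the predicted projection against the header, scores
no-reference image quality, and emits a byte-reproducible JSON/HTML report.
A built-in shortcut-learning experiment (`text_removal_experiment()`)
quantifies how much a classifier leans on burned-in text and shows that
inpainting removes the shortcut.

Because no patient data can ship with the package, all verification runs on a
parametric chest phantom (`generate_phantom()`, `generate_dataset()`) whose
truth object carries the exact crop box, rotation, text mask, lung mask, and
labels — so tests compare against oracles, not eyeballs.

## Worked example

```r
library(radqc)

# Generate a small synthetic study set (DICOM files + curation table on disk)
td <- file.path(tempdir(), "demo")
ds <- generate_dataset(6, dataset_config(text_prob = 1), seed = 7, out_dir = td)

# Run the full QC pipeline over the DICOM directory
report <- run_pipeline(file.path(td, "dicom"), autoqc_config(),
                       mode = "review", seed = 1)
subset(report$qc_table, action != "pass")[, c("image_id", "stage", "action", "reasons")]
#>    image_id   stage          action      reasons
#> 21 IMG00003 quality flag_for_review low_contrast
#> 35 IMG00005 quality flag_for_review      blurred

recommend_review_subset(report$qc_table)
#> [1] "IMG00003" "IMG00005"

build_report(report, file.path(td, "qc"))
list.files(file.path(td, "qc"))
#> [1] "report.html" "report.json"

# Annotation removal on a single image
img <- apply_windowing(ds$items[[1]]$record$image)
m <- detect_annotations(img)
sum(m$mask)
#> [1] 396
clean <- inpaint(img, m)
identical(clean[!m$mask], img[!m$mask])   # untouched pixels are bit-identical
#> [1] TRUE
```

Other entry points:

- `apply_windowing()`, `intensity_stats()`, `standardized_mean_difference()` —
  intensity harmonization and its measurement
- `detect_border_crop()`, `crop_image()`, `correct_rotation()`,
  `aspect_ratio_check()` — geometric standardization
- `train_projection_model()`, `parse_series_description()`,
  `consistency_check()` — projection vs header consistency
- `quality_metrics()`, `quality_flag()` — no-reference quality screening
- `apply_inclusion_filters()`, `select_one_per_patient()`,
  `stratified_partition()` — dataset curation with exact 64/16/20
  largest-remainder splits
- `classification_metrics()`, `bootstrap_ci()`, `saliency_map()`,
  `mask_iou()` — evaluation
- `text_removal_experiment()` — the shortcut-learning study

See `vignettes/autoqc-methods.Rmd` for the methods description.

## Running the tests

The suite uses testthat (edition 3) and runs against the installed package:

```sh
Rscript -e 'library(testthat); library(radqc); test_dir("tests/testthat")'
```

`tests/testthat/test-acceptance.R` contains one block per acceptance
criterion: configuration constants, partition arithmetic against a
largest-remainder oracle, harmonization direction on a two-manufacturer set,
annotation removal rates on 300 text phantoms, crop/rotation exactness on
500/200 phantoms, the seven evaluation metrics against a brute-force
confusion-matrix oracle on 1000 random instances, the shortcut experiment,
and byte-identical end-to-end reports. The full suite takes about 3 minutes
on one CPU.

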
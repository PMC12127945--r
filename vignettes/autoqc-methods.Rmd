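---
title: "Automated quality control for chest radiographs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated quality control for chest radiographs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radqc)
```

## Motivation

Chest radiographs collected across hospitals, scanner manufacturers, and
years arrive with inconsistent intensity encodings, black collimation
borders, uniform padding, occasional 90-degree rotations, and burned-in
text annotations (projection labels, laterality markers, technical
parameters). Left uncorrected, these artifacts do two kinds of damage to
downstream machine-learning models:

1. **Distribution shift.** Manufacturer-specific gamma curves and offsets
   make the same anatomy look different across sites, inflating
   inter-site variability.
2. **Shortcut learning.** Burned-in text is often correlated with the
   prediction target (for example, projection labels or ward markers), so
   a model can reach high validation accuracy by reading the text rather
   than the anatomy — and then fail when deployed somewhere the text is
   absent or different.

`radqc` implements a deterministic, rule-based QC pipeline that
standardizes intensity, geometry, and annotations, screens image quality,
and — crucially — ships with a fully synthetic phantom generator so every
stage can be verified against exact ground truth without any patient
data.

## Pipeline stages

`run_pipeline()` applies the following stages to every image in a
directory, recording a per-stage verdict (`pass`, `flag_for_review`, or
`exclude`) with machine-readable reasons and evidence:

### 1. Ingestion

Uncompressed little-endian DICOM (explicit or implicit VR) and PNG with a
JSON metadata sidecar are supported. Pixels are mapped to a canonical
`[0, 1]` scale where bright means radiodense; `MONOCHROME1` images are
inverted on read so the canonical polarity always holds. Files that fail
to decode are excluded with reason `decode_error` and never abort the
batch.

### 2. Intensity standardization

`apply_windowing()` applies a value-of-interest (VOI) window — a linear
ramp from `center - width/2` to `center + width/2`, clamped to `[0, 1]`.
When the file header carries a window, that window is used; otherwise an
automatic window is derived from the 1st and 99th percentiles of the
non-padding pixels. `intensity_stats()` summarizes each image (mean, SD,
coefficient of variation, 8-bit histogram entropy), and
`standardized_mean_difference()` quantifies residual inter-manufacturer
shift. Applying the header windows compresses manufacturer-specific
contrast stretches toward a common scale, which is what drives the
decrease in CV, SD, entropy, and inter-manufacturer SMD measured in the
acceptance suite.

### 3. Geometric standardization

`detect_border_crop()` finds the tightest box containing diagnostic
content by first stripping exact-zero padding, then trimming
near-constant dark collimation bands (below the 5th-percentile-based
threshold), capped at 45% of each dimension so anatomy is never eaten.
Cropping is exactly idempotent. `correct_rotation()` tests the four
90-degree orientations and picks the one maximizing an anatomy prior
(vertical spine/mediastinum energy and left-right symmetry).
`aspect_ratio_check()` flags images whose height/width ratio falls
outside `[0.85, 1.48]`.

### 4. Annotation handling

`detect_annotations()` finds burned-in text: a white top-hat transform
(disc structuring element) isolates small bright structures; pixels that
are both bright (≥ 0.95) and top-hat-positive, or very strongly
top-hat-positive, are grouped into connected components and filtered by
glyph-like geometry (height between 1% and 10% of the image, bounding-box
fill ratio ≤ 0.82, limited width). The top-hat is suppressed within one
brush radius of the frame edge, where morphological opening is
unreliable. The final mask is dilated by 2 px so anti-aliased glyph
fringes are covered.

`inpaint()` fills the mask by onion-peel initialization followed by
Jacobi relaxation of Laplace's equation inside each component's bounding
box — a discrete harmonic fill. Pixels outside the mask are returned
bit-identical. If more than half the image is masked the function refuses
with a classed condition (`radqc_inpaint_refused`) rather than fabricate
anatomy.

### 5. Consistency and projection

A ridge-regularized logistic model (`train_projection_model()`) on
coarse 32×32 intensity features plus symmetry/profile summaries predicts
frontal vs lateral projection. `parse_series_description()` extracts the
header's claim (whole-token matching, lateral precedence), and
`consistency_check()` flags disagreements (`metadata_mismatch`) for
human review rather than silently trusting either source.

### 6. No-reference quality screening

`quality_metrics()` computes gradient-energy sharpness, a robust
contrast range, a blur index (correlation between the image and a
smoothed copy), and the residual border fraction. `quality_flag()`
compares these to frozen thresholds calibrated once on clean,
header-windowed, cropped phantoms; reasons are `over_sharpened`,
`low_contrast`, `blurred`, and `large_border`.

### 7. Reporting

`build_report()` writes a canonical, byte-reproducible `report.json`
(sorted keys and rows, fixed digit handling) plus a small static
`report.html`. `recommend_review_subset()` ranks flagged images by the
number of flagging stages, then the number of distinct reasons, then id.

## Dataset curation

Given a curation table, `apply_inclusion_filters()` drops rows with
missing manufacturer, deviation index, sex, age, or ethnicity (zero is a
value, not missing; unparseable ages count as missing);
`age_midpoint()` maps range strings such as `"40-49"` to midpoints;
`select_one_per_patient()` keeps one seeded-random image per patient;
and `stratified_partition()` splits 64/16/20 into train/tune/test within
manufacturer strata using largest-remainder rounding, so the totals are
exact for any n.

## Synthetic phantoms and ground truth

`phantom_spec()`/`generate_phantom()` draw a parametric chest phantom
(thorax, lungs, spine, ribs, heart for frontal; single lung field and
sternum-spine profile for lateral) with configurable gamma, offset,
noise, blur, rotation, padding, collimation, and burned-in text rendered
from a built-in 5×7 glyph font. The returned truth object carries the
exact crop box, rotation, text mask, lung mask, and labels, enabling
oracle-exact tests. `generate_dataset()` wraps this into a reproducible
multi-manufacturer study set and can write DICOM files plus a curation
table to disk.

## The shortcut-learning experiment

`text_removal_experiment()` quantifies how much a classifier leans on
burned-in text. Training images carry projection-consistent text tokens
while the anatomy matches the label only with probability
`anatomy_rho` (default 0.75), so text is the more reliable cue. Three
models are trained on the same images: unmodified (`original`), with
detected text inpainted (`inpainted`), and with detected text boxes
zeroed (`zero_box`). Each is evaluated on test sets with and without
text. The headline quantities are the accuracy drop when text is removed
at test time (large for `original`, small for the cleaned models) and
the mean IoU between occlusion-saliency masks (`saliency_map()`,
`saliency_mask()`) and the true text regions — lowest for the
`inpainted` model, confirming it no longer looks where the text was.

## Determinism

Every stochastic step takes an explicit seed, all file listings are
sorted, and JSON is written canonically, so identical inputs, config,
and seed produce byte-identical reports. This is asserted end-to-end in
the acceptance suite.
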
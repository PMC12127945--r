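#' Read a radiograph from DICOM or PNG
#'
#' Decodes the pixel data, applies rescale slope/intercept, normalises over
#' the stored value range to `[0, 1]` (so zero padding stays at exactly 0),
#' and inverts MONOCHROME1 images so that after ingest higher values are
#' always radiodense (air dark, bone bright). Header fields the pipeline
#' inspects are collected into a [metadata_record]; absent fields become
#' `NA`, never zero.
#'
#' PNG files are read as an 8/16-bit grayscale fallback; their metadata is
#' taken from a JSON sidecar (`<name>.json`) with the same field names.
#'
#' @param path path to a `.dcm` or `.png` file.
#' @return a [radiograph_record], or an object of class `ingest_failure`
#'   carrying an `exclude`/`decode_error` [qc_result] when the file cannot
#'   be decoded. Decode problems never raise, so one corrupt file cannot
#'   halt a batch.
#' @export
read_radiograph <- function(path) {
  tryCatch({
    ext <- tolower(tools::file_ext(path))
    if (ext == "png") {
      .read_png_record(path)
    } else {
      .read_dicom_record(path)
    }
  }, error = function(e) {
    structure(
      list(source = path,
           message = conditionMessage(e),
           result = qc_result("ingest", "exclude", reasons = "decode_error")),
      class = "ingest_failure"
    )
  })
}

.read_dicom_record <- function(path) {
  d <- dcm_read(path)
  # modality rescale then min-max over the stored value range: with slope s
  # and intercept b the representable range is [b, s*vmax + b], so the
  # normalised value reduces to stored/vmax and padding at 0 stays at 0.
  vmax <- 2^d$bits_stored - 1
  img <- clamp01(d$stored / vmax)
  if (identical(d$photometric, "MONOCHROME1")) img <- 1 - img
  md <- metadata_record(
    patient_id = if (is.na(d$patient_id)) "unknown" else d$patient_id,
    manufacturer = d$manufacturer,
    deviation_index = d$deviation_index,
    sex = d$sex, age = d$age, ethnicity = d$ethnicity,
    series_description = d$series_description,
    photometric = d$photometric,
    bits_stored = d$bits_stored
  )
  rec <- radiograph_record(img, md, source = path)
  rec <- record_log(rec, sprintf("ingest:dicom:%s:%d-bit", d$photometric, d$bits_stored))
  if (!is.null(d$window)) {
    # header window is stored in DN units; express it on the canonical [0,1]
    # scale, mirrored when the stored polarity was inverted at ingest
    center <- d$window$center / vmax
    if (identical(d$photometric, "MONOCHROME1")) center <- 1 - center
    attr(rec, "window") <- list(center = center, width = d$window$width / vmax)
  }
  rec
}

.read_png_record <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  md_list <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  pick <- function(name, default = NA) {
    v <- md_list[[name]]
    if (is.null(v)) default else v
  }
  md <- metadata_record(
    patient_id = pick("patient_id", "unknown"),
    manufacturer = pick("manufacturer", NA_character_),
    deviation_index = pick("deviation_index", NA_real_),
    sex = pick("sex", NA_character_),
    age = pick("age", NA),
    ethnicity = pick("ethnicity", NA_character_),
    series_description = pick("series_description", NA_character_),
    photometric = pick("photometric", "MONOCHROME2"),
    bits_stored = pick("bits_stored", 8L)
  )
  img <- clamp01(img)
  if (identical(md$photometric, "MONOCHROME1")) img <- 1 - img
  rec <- radiograph_record(img, md, source = path)
  record_log(rec, "ingest:png")
}

#' Write a radiograph to DICOM (or PNG with JSON sidecar)
#'
#' Quantises the `[0, 1]` image to the metadata's stored bit depth and writes
#' an uncompressed explicit-VR little-endian DICOM file whose header fields
#' round-trip through [read_radiograph]. When the record's photometric
#' interpretation is MONOCHROME1 the stored values are inverted accordingly,
#' so read-back reproduces the canonical bright-is-dense image.
#'
#' @param record a [radiograph_record].
#' @param path output path; a `.png` extension selects the PNG fallback
#'   (8-bit pixels plus a JSON metadata sidecar).
#' @param window optional list with `center` and `width` in `[0, 1]` written
#'   as the VOI window of the file.
#' @return the output path, invisibly.
#' @export
write_radiograph <- function(record, path, window = NULL) {
  stopifnot(inherits(record, "radiograph_record"))
  md <- record$metadata
  if (tolower(tools::file_ext(path)) == "png") {
    img <- record$image
    if (identical(md$photometric, "MONOCHROME1")) img <- 1 - img
    png::writePNG(img, path)
    sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
    fields <- md[c("patient_id", "manufacturer", "deviation_index", "sex",
                   "age", "ethnicity", "series_description", "photometric",
                   "bits_stored")]
    jsonlite::write_json(fields, sidecar, auto_unbox = TRUE, na = "null",
                         digits = NA)
    return(invisible(path))
  }
  vmax <- 2L^md$bits_stored - 1L
  stored <- matrix(as.integer(round(record$image * vmax)),
                   nrow = nrow(record$image))
  if (identical(md$photometric, "MONOCHROME1")) stored <- vmax - stored
  scaled_window <- NULL
  if (!is.null(window)) {
    # window centre follows the stored polarity
    center <- if (identical(md$photometric, "MONOCHROME1")) 1 - window$center else window$center
    scaled_window <- list(center = center * vmax, width = window$width * vmax)
  }
  dcm_write(path, stored, md, window = scaled_window)
  invisible(path)
}
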
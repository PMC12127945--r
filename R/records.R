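#' Per-stage quality-control verdict
#'
#' Every pipeline stage emits one `qc_result`: the stage name, an action
#' (`pass`, `flag_for_review` or `exclude`), machine-readable reason codes and
#' the numeric evidence that triggered them.
#'
#' @param stage character stage name.
#' @param action one of `"pass"`, `"flag_for_review"`, `"exclude"`.
#' @param reasons character vector of reason codes; must be non-empty unless
#'   the action is `pass`.
#' @param evidence named list of numeric evidence values.
#' @return an object of class `qc_result`.
#' @export
qc_result <- function(stage, action = c("pass", "flag_for_review", "exclude"),
                      reasons = character(), evidence = list()) {
  action <- match.arg(action)
  if (action != "pass" && length(reasons) == 0L) {
    stop("non-pass qc_result requires at least one reason code")
  }
  structure(
    list(stage = stage, action = action,
         reasons = as.character(reasons), evidence = evidence),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> stage=%s action=%s", x$stage, x$action))
  if (length(x$reasons)) cat(" reasons=", paste(x$reasons, collapse = ","))
  cat("\n")
  invisible(x)
}

#' Header metadata inspected by the pipeline
#'
#' Holds the DICOM header fields the curation and consistency stages use.
#' Absent fields are `NA`, never zero: the curation rules must distinguish
#' a missing deviation index from a measured value of zero.
#'
#' @param patient_id patient identifier (required, non-empty).
#' @param manufacturer,series_description,ethnicity free-text fields or `NA`.
#' @param deviation_index numeric exposure index or `NA`.
#' @param sex `"M"`, `"F"`, `"other"` or `NA`.
#' @param age numeric years, an age-range string such as `"40-49"`, or `NA`.
#' @param photometric `"MONOCHROME1"` or `"MONOCHROME2"`.
#' @param bits_stored integer in `[8, 16]`.
#' @return an object of class `metadata_record`.
#' @export
metadata_record <- function(patient_id,
                            manufacturer = NA_character_,
                            deviation_index = NA_real_,
                            sex = NA_character_,
                            age = NA,
                            ethnicity = NA_character_,
                            series_description = NA_character_,
                            photometric = "MONOCHROME2",
                            bits_stored = 16L) {
  if (is_missing_field(patient_id)) stop("patient_id must be non-empty")
  if (!photometric %in% c("MONOCHROME1", "MONOCHROME2")) {
    stop("photometric must be MONOCHROME1 or MONOCHROME2")
  }
  bits_stored <- as.integer(bits_stored)
  if (bits_stored < 8L || bits_stored > 16L) stop("bits_stored must be in [8, 16]")
  if (!is.na(sex) && !sex %in% c("M", "F", "other")) sex <- "other"
  structure(
    list(patient_id = as.character(patient_id),
         manufacturer = manufacturer,
         deviation_index = deviation_index,
         sex = sex,
         age = age,
         ethnicity = ethnicity,
         series_description = series_description,
         photometric = photometric,
         bits_stored = bits_stored),
    class = "metadata_record"
  )
}

#' One radiograph with metadata and accumulated QC results
#'
#' The canonical in-memory representation used throughout the pipeline:
#' a 2-D intensity matrix in `[0, 1]` with bright values radiodense (bone
#' bright, air dark, regardless of the stored photometric interpretation),
#' plus header metadata, the ordered QC verdicts, and an append-only
#' transform log.
#'
#' @param image numeric matrix with at least 32 rows and 32 columns, all
#'   values finite and in `[0, 1]`.
#' @param metadata a [metadata_record].
#' @param source source path or label.
#' @return an object of class `radiograph_record`.
#' @export
radiograph_record <- function(image, metadata, source = NA_character_) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (nrow(image) < 32L || ncol(image) < 32L) {
    stop("image must have at least 32 rows and 32 columns")
  }
  if (!all(is.finite(image)) || min(image) < 0 || max(image) > 1) {
    stop("image values must be finite and in [0, 1]")
  }
  if (!inherits(metadata, "metadata_record")) stop("metadata must be a metadata_record")
  structure(
    list(image = image, metadata = metadata, qc_results = list(),
         provenance = list(source = source, log = character())),
    class = "radiograph_record"
  )
}

# Append-only helpers -------------------------------------------------------

#' @keywords internal
record_log <- function(record, entry) {
  record$provenance$log <- c(record$provenance$log, entry)
  record
}

#' @keywords internal
record_result <- function(record, result) {
  stopifnot(inherits(result, "qc_result"))
  record$qc_results <- c(record$qc_results, list(result))
  record
}

#' @export
print.radiograph_record <- function(x, ...) {
  cat(sprintf("<radiograph_record> %dx%d patient=%s photometric=%s\n",
              nrow(x$image), ncol(x$image),
              x$metadata$patient_id, x$metadata$photometric))
  if (length(x$qc_results)) {
    for (r in x$qc_results) print(r)
  }
  invisible(x)
}
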
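# Minimal DICOM codec: uncompressed explicit/implicit VR little endian,
# single-frame grayscale. Covers the header fields the QC pipeline inspects.
# Compressed transfer syntaxes and sequences with undefined length are
# rejected with an error, which the ingest layer converts into a structured
# decode_error exclusion.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"

.u16le <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.u32le <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

.pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

.str_bytes <- function(s, pad = as.raw(0x20)) {
  .pad_even(charToRaw(as.character(s)), pad)
}

# One data element in explicit VR little endian.
.dcm_element <- function(group, elem, vr, value) {
  header <- c(.u16le(group), .u16le(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(header, as.raw(c(0, 0)), .u32le(length(value)), value)
  } else {
    if (length(value) > 65534L) stop("short-VR element too long")
    c(header, .u16le(length(value)), value)
  }
}

.dcm_str_el <- function(group, elem, vr, s) {
  pad <- if (vr == "UI") as.raw(0x00) else as.raw(0x20)
  .dcm_element(group, elem, vr, .str_bytes(s, pad))
}

.dcm_us_el <- function(group, elem, x) .dcm_element(group, elem, "US", .u16le(x))

.dcm_ds_el <- function(group, elem, x) {
  .dcm_str_el(group, elem, "DS", sprintf("%.10g", x))
}

# Write a single-frame grayscale DICOM file (explicit VR little endian).
# `stored` is an integer matrix of stored pixel values (row-major raster),
# already in the polarity implied by `meta$photometric`.
#' @keywords internal
dcm_write <- function(path, stored, meta, window = NULL) {
  bits <- meta$bits_stored
  bits_alloc <- if (bits <= 8L) 8L else 16L
  nr <- nrow(stored); nc <- ncol(stored)
  vmax <- 2L^bits - 1L
  v <- as.integer(t(stored))            # DICOM rasters are row-major
  if (min(v) < 0L || max(v) > vmax) stop("stored values out of range for bits_stored")

  pix <- if (bits_alloc == 8L) {
    as.raw(v)
  } else {
    writeBin(v, raw(), size = 2L, endian = "little")
  }

  ds <- c(
    .dcm_str_el(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    .dcm_str_el(0x0008, 0x0018, "UI", paste0("1.2.826.0.1.3680043.9.7433.", meta$patient_id_hash %||% "1")),
    .dcm_str_el(0x0008, 0x0060, "CS", "DX")
  )
  if (!is_missing_field(meta$manufacturer)) {
    ds <- c(ds, .dcm_str_el(0x0008, 0x0070, "LO", meta$manufacturer))
  }
  if (!is_missing_field(meta$series_description)) {
    ds <- c(ds, .dcm_str_el(0x0008, 0x103E, "LO", meta$series_description))
  }
  ds <- c(ds, .dcm_str_el(0x0010, 0x0020, "LO", meta$patient_id))
  if (!is_missing_field(meta$sex)) {
    ds <- c(ds, .dcm_str_el(0x0010, 0x0040, "CS", meta$sex))
  }
  if (!is_missing_field(meta$age)) {
    age <- meta$age
    age_str <- if (is.numeric(age)) sprintf("%03dY", as.integer(round(age))) else as.character(age)
    ds <- c(ds, .dcm_str_el(0x0010, 0x1010, "AS", age_str))
  }
  if (!is_missing_field(meta$ethnicity)) {
    ds <- c(ds, .dcm_str_el(0x0010, 0x2160, "SH", meta$ethnicity))
  }
  if (!is_missing_field(meta$deviation_index)) {
    ds <- c(ds, .dcm_ds_el(0x0018, 0x1413, meta$deviation_index))
  }
  ds <- c(ds,
    .dcm_us_el(0x0028, 0x0002, 1L),
    .dcm_str_el(0x0028, 0x0004, "CS", meta$photometric),
    .dcm_us_el(0x0028, 0x0010, nr),
    .dcm_us_el(0x0028, 0x0011, nc),
    .dcm_us_el(0x0028, 0x0100, bits_alloc),
    .dcm_us_el(0x0028, 0x0101, bits),
    .dcm_us_el(0x0028, 0x0102, bits - 1L),
    .dcm_us_el(0x0028, 0x0103, 0L)
  )
  if (!is.null(window)) {
    ds <- c(ds,
      .dcm_ds_el(0x0028, 0x1050, window$center),
      .dcm_ds_el(0x0028, 0x1051, window$width))
  }
  ds <- c(ds,
    .dcm_ds_el(0x0028, 0x1052, 0),
    .dcm_ds_el(0x0028, 0x1053, 1),
    .dcm_element(0x7FE0, 0x0010, if (bits_alloc == 8L) "OB" else "OW", pix)
  )

  meta_group <- c(
    .dcm_element(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    .dcm_str_el(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    .dcm_str_el(0x0002, 0x0003, "UI", "1.2.826.0.1.3680043.9.7433.0.1"),
    .dcm_str_el(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
    .dcm_str_el(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9.7433.0")
  )
  meta_group <- c(.dcm_element(0x0002, 0x0000, "UL", .u32le(length(meta_group))),
                  meta_group)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta_group, ds), con)
  invisible(path)
}

# Implicit-VR dictionary for the tags the pipeline reads.
.IMPLICIT_VR <- c(
  "00080060" = "CS", "00080070" = "LO", "0008103e" = "LO",
  "00100020" = "LO", "00100040" = "CS", "00101010" = "AS",
  "00102160" = "SH", "00181413" = "DS",
  "00280002" = "US", "00280004" = "CS", "00280010" = "US", "00280011" = "US",
  "00280100" = "US", "00280101" = "US", "00280102" = "US", "00280103" = "US",
  "00281050" = "DS", "00281051" = "DS", "00281052" = "DS", "00281053" = "DS",
  "7fe00010" = "OW"
)

.read_u16 <- function(b, pos) {
  as.integer(b[pos]) + 256L * as.integer(b[pos + 1L])
}
.read_u32 <- function(b, pos) {
  as.integer(b[pos]) + 256 * as.integer(b[pos + 1L]) +
    65536 * as.integer(b[pos + 2L]) + 16777216 * as.integer(b[pos + 3L])
}

# Parse a DICOM stream into a named list of element values keyed by
# lower-case "ggggeeee". String VRs are decoded; US as integer; pixel data
# kept raw.
.dcm_parse <- function(bytes, pos, end, explicit) {
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN", "UC", "UR", "OD", "OL")
  str_vrs <- c("CS", "LO", "SH", "AS", "DS", "IS", "UI", "PN", "LT", "ST", "DA", "TM", "AE")
  while (pos + 7 <= end) {
    group <- .read_u16(bytes, pos); elem <- .read_u16(bytes, pos + 2L)
    key <- sprintf("%04x%04x", group, elem)
    if (explicit || group == 0x0002) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- .read_u32(bytes, pos + 8L); hdr <- 12L
      } else {
        len <- .read_u16(bytes, pos + 6L); hdr <- 8L
      }
    } else {
      vr <- .IMPLICIT_VR[key]
      if (is.na(vr)) vr <- "UN"
      len <- .read_u32(bytes, pos + 4L); hdr <- 8L
    }
    if (len == 4294967295 || (!explicit && len > end)) {
      stop("unsupported undefined-length or corrupt element at tag ", key)
    }
    vstart <- pos + hdr
    if (vstart + len - 1L > end) stop("element ", key, " runs past end of file")
    val_raw <- if (len > 0L) bytes[vstart:(vstart + len - 1L)] else raw(0)
    if (key == "7fe00010") {
      out[[key]] <- val_raw
    } else if (vr %in% str_vrs) {
      out[[key]] <- trimws(rawToChar(val_raw[val_raw != as.raw(0)]))
    } else if (vr == "US") {
      out[[key]] <- .read_u16(val_raw, 1L)
    } else if (vr == "UL") {
      out[[key]] <- .read_u32(val_raw, 1L)
    }
    pos <- vstart + len
  }
  out
}

# Read a DICOM file into a raw image matrix plus metadata list.
#' @keywords internal
dcm_read <- function(path) {
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM magic)")
  }
  # file meta group is always explicit VR LE; find its extent
  pos <- 133L
  if (.read_u16(bytes, pos) != 0x0002) stop("missing file meta group")
  glen <- .read_u32(bytes, pos + 8L)
  meta_end <- pos + 12L + glen - 1L
  meta <- .dcm_parse(bytes, pos, meta_end, explicit = TRUE)
  ts <- meta[["00020010"]] %||% TS_EXPLICIT_LE
  if (!ts %in% c(TS_EXPLICIT_LE, TS_IMPLICIT_LE)) {
    stop("unsupported transfer syntax: ", ts)
  }
  el <- .dcm_parse(bytes, meta_end + 1L, length(bytes), explicit = ts == TS_EXPLICIT_LE)

  nr <- el[["00280010"]]; nc <- el[["00280011"]]
  bits_alloc <- el[["00280100"]] %||% 16L
  bits <- el[["00280101"]] %||% bits_alloc
  if (is.null(nr) || is.null(nc) || is.null(el[["7fe00010"]])) {
    stop("missing image dimensions or pixel data")
  }
  pix_raw <- el[["7fe00010"]]
  n_expect <- nr * nc * (bits_alloc %/% 8L)
  if (length(pix_raw) < n_expect) stop("truncated pixel data")
  v <- if (bits_alloc == 8L) {
    as.integer(pix_raw[seq_len(n_expect)])
  } else {
    readBin(pix_raw, "integer", n = nr * nc, size = 2L, signed = FALSE,
            endian = "little")
  }
  stored <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)

  num_or_na <- function(key) {
    x <- el[[key]]
    if (is.null(x) || !nzchar(x)) NA_real_ else suppressWarnings(as.numeric(x))
  }
  chr_or_na <- function(key) {
    x <- el[[key]]
    if (is.null(x) || !nzchar(x)) NA_character_ else x
  }
  age_raw <- chr_or_na("00101010")
  age <- if (is.na(age_raw)) {
    NA
  } else if (grepl("^[0-9]+Y?$", age_raw)) {
    as.numeric(sub("Y$", "", age_raw))
  } else {
    age_raw
  }
  window <- NULL
  if (!is.na(num_or_na("00281050")) && !is.na(num_or_na("00281051"))) {
    window <- list(center = num_or_na("00281050"), width = num_or_na("00281051"))
  }
  list(
    stored = stored,
    bits_stored = bits,
    rescale_slope = if (is.na(num_or_na("00281053"))) 1 else num_or_na("00281053"),
    rescale_intercept = if (is.na(num_or_na("00281052"))) 0 else num_or_na("00281052"),
    photometric = if (is.na(chr_or_na("00280004"))) "MONOCHROME2" else chr_or_na("00280004"),
    window = window,
    patient_id = chr_or_na("00100020"),
    manufacturer = chr_or_na("00080070"),
    series_description = chr_or_na("0008103e"),
    sex = chr_or_na("00100040"),
    age = age,
    ethnicity = chr_or_na("00102160"),
    deviation_index = num_or_na("00181413")
  )
}
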
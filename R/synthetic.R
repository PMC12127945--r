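# Synthetic chest phantoms -------------------------------------------------
#
# Geometric chest-like phantoms with complete ground truth. They are not
# anatomically realistic; they carry exactly the properties the QC stages
# key on: vertical mirror symmetry (frontal) vs asymmetry (lateral), a
# bright bottom (abdomen), dark lung fields, burned-in text with exact truth
# masks, constant padding, near-black collimation bands, 90-degree
# rotations, blur/noise degradations and manufacturer-specific gamma/offset
# intensity distortions.

# 5x7 stroke font; glyphs are sparse (stroke-like) by construction so truth
# masks are exact and detection geometry is well defined without fonts.
.GLYPHS <- list(
  A = c(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  P = c("####.", "#...#", "#...#", "####.", "#....", "#....", "#...."),
  L = c("#....", "#....", "#....", "#....", "#....", "#....", "#####"),
  T = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
  R = c("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
  E = c("#####", "#....", "#....", "####.", "#....", "#....", "#####"),
  C = c(".####", "#....", "#....", "#....", "#....", "#....", ".####"),
  O = c(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  "1" = c("..#..", ".##..", "..#..", "..#..", "..#..", "..#..", ".###."),
  "2" = c(".###.", "#...#", "....#", "..##.", ".#...", "#....", "#####")
)

.glyph_matrix <- function(ch) {
  g <- .GLYPHS[[ch]]
  if (is.null(g)) g <- .GLYPHS[["O"]]
  do.call(rbind, lapply(g, function(row) strsplit(row, "")[[1]] == "#"))
}

# Render text into a logical mask at (row, col) top-left, integer scale.
#' @keywords internal
render_text_mask <- function(nr, nc, text, row, col, scale = 2L) {
  mask <- matrix(FALSE, nr, nc)
  chars <- strsplit(toupper(text), "")[[1]]
  x <- col
  for (ch in chars) {
    if (ch == " ") { x <- x + 3L * scale; next }
    g <- .glyph_matrix(ch)
    gm <- g[rep(seq_len(nrow(g)), each = scale),
            rep(seq_len(ncol(g)), each = scale), drop = FALSE]
    r1 <- row + nrow(gm) - 1L; c1 <- x + ncol(gm) - 1L
    if (r1 > nr || c1 > nc || row < 1L || x < 1L) {
      stop("text item extends outside the frame")
    }
    mask[row:r1, x:c1] <- mask[row:r1, x:c1] | gm
    x <- c1 + scale + 1L
  }
  mask
}

#' Parameterisation of one synthetic radiograph
#'
#' Full ground-truth specification of a phantom: projection, geometry,
#' burned-in text items, border widths, rotation, degradations and header
#' values. Degradations are applied in a fixed order: anatomy, gamma/offset,
#' text, blur, noise, collimation, padding, rotation.
#'
#' @param projection `"frontal"` or `"lateral"`.
#' @param size `c(rows, cols)` of the anatomy content (before borders).
#' @param text_items list of lists with `text`, `pos` (`c(row, col)` or a
#'   corner name `"tl"`, `"tr"`, `"bl"`, `"br"`), `intensity` and `scale`.
#' @param pad_width constant zero-padding width (all sides).
#' @param collim_widths near-black collimation widths `c(top, bottom, left,
#'   right)`.
#' @param collim_value intensity of the collimation band.
#' @param rotation clockwise rotation in `{0, 90, 180, 270}` applied last.
#' @param blur_sigma Gaussian blur sigma in pixels (0 = none).
#' @param noise_sd additive Gaussian noise sd.
#' @param gamma,offset manufacturer intensity distortion
#'   (`clamp(x^gamma + offset)`).
#' @param anatomy_jitter relative jitter of lung position/size (controls how
#'   separable frontal vs lateral anatomy is).
#' @param header named list of [metadata_record] fields.
#' @param seed integer RNG seed; the phantom is deterministic given the spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(projection = c("frontal", "lateral"),
                         size = c(192L, 192L),
                         text_items = list(),
                         pad_width = 0L,
                         collim_widths = c(0L, 0L, 0L, 0L),
                         collim_value = 0.02,
                         rotation = 0L,
                         blur_sigma = 0,
                         noise_sd = 0.01,
                         gamma = 1,
                         offset = 0,
                         anatomy_jitter = 0.1,
                         header = list(patient_id = "P0001"),
                         seed = 1L) {
  projection <- match.arg(projection)
  size <- as.integer(size)
  stopifnot(length(size) == 2L, all(size >= 64L))
  pad_width <- as.integer(pad_width)
  collim_widths <- as.integer(rep(collim_widths, length.out = 4L))
  if (pad_width < 0L || any(collim_widths < 0L)) stop("border widths must be >= 0")
  total_r <- pad_width * 2L + collim_widths[1] + collim_widths[2]
  total_c <- pad_width * 2L + collim_widths[3] + collim_widths[4]
  if (total_r >= 0.45 * (size[1] + total_r) || total_c >= 0.45 * (size[2] + total_c)) {
    stop("border widths exceed 45% of a dimension")
  }
  if (!rotation %in% c(0L, 90L, 180L, 270L)) stop("rotation must be a multiple of 90")
  stopifnot(blur_sigma >= 0, noise_sd >= 0, gamma > 0)
  structure(
    list(projection = projection, size = size, text_items = text_items,
         pad_width = pad_width, collim_widths = collim_widths,
         collim_value = collim_value, rotation = as.integer(rotation),
         blur_sigma = blur_sigma, noise_sd = noise_sd, gamma = gamma,
         offset = offset, anatomy_jitter = anatomy_jitter,
         header = header, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

.ellipse_mask <- function(nr, nc, cr, cc, rr, rc) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((r - cr) / rr)^2 + ((c - cc) / rc)^2 <= 1
}

.phantom_anatomy <- function(projection, nr, nc, jitter) {
  j <- function(scale = 1) stats::rnorm(1L, 0, jitter * scale)
  base <- 0.36 +
    0.03 * outer(sin(seq(0, 2 * pi, length.out = nr) * stats::runif(1, 0.5, 1.5)),
                 cos(seq(0, 2 * pi, length.out = nc) * stats::runif(1, 0.5, 1.5)))
  img <- base
  lung <- matrix(FALSE, nr, nc)
  if (projection == "frontal") {
    cy <- (0.42 + j(0.3)) * nr
    rx <- (0.24 + j(0.3) * 0.24) * nr
    ry <- (0.145 + j(0.3) * 0.145) * nc
    dx <- (0.225 + j(0.2) * 0.225) * nc
    left <- .ellipse_mask(nr, nc, cy, nc / 2 - dx, rx, ry)
    right <- .ellipse_mask(nr, nc, cy, nc / 2 + dx, rx, ry)
    lung <- left | right
    img[lung] <- 0.12
    med <- abs(matrix(seq_len(nc), nr, nc, byrow = TRUE) - nc / 2) < 0.065 * nc &
      matrix(seq_len(nr), nr, nc) > 0.12 * nr &
      matrix(seq_len(nr), nr, nc) < 0.80 * nr
    img[med & !lung] <- 0.72
  } else {
    cy <- (0.40 + j(0.3)) * nr
    cx <- (0.42 + j(0.3)) * nc
    lung <- .ellipse_mask(nr, nc, cy, cx, (0.26 + j(0.2) * 0.26) * nr,
                          (0.23 + j(0.2) * 0.23) * nc)
    img[lung] <- 0.14
    spine <- matrix(seq_len(nc), nr, nc, byrow = TRUE) > 0.70 * nc &
      matrix(seq_len(nc), nr, nc, byrow = TRUE) < 0.82 * nc
    img[spine] <- 0.70
  }
  abd <- matrix(seq_len(nr), nr, nc) > (0.80 + j(0.1) * 0.05) * nr
  img[abd] <- pmax(img[abd], 0.78)
  list(image = clamp01(img), lung = lung)
}

.resolve_text_pos <- function(pos, nr, nc, text, scale) {
  w <- 0L
  for (ch in strsplit(toupper(text), "")[[1]]) {
    w <- w + if (ch == " ") 3L * scale else 6L * scale + 1L
  }
  h <- 7L * scale
  margin <- max(4L, scale * 2L)
  if (is.character(pos)) {
    switch(pos,
      tl = c(margin, margin),
      tr = c(margin, nc - w - margin),
      bl = c(nr - h - margin, margin),
      br = c(nr - h - margin, nc - w - margin),
      stop("unknown corner: ", pos))
  } else {
    as.integer(pos)
  }
}

.pad_matrix <- function(m, top, bottom, left, right, value) {
  nr <- nrow(m) + top + bottom
  nc <- ncol(m) + left + right
  out <- matrix(value, nr, nc)
  out[(top + 1L):(top + nrow(m)), (left + 1L):(left + ncol(m))] <- m
  out
}

#' Generate one phantom radiograph with ground truth
#'
#' Deterministic given the spec's seed. Degradations are applied in the
#' fixed order anatomy, gamma/offset, text, blur, noise, collimation,
#' padding, rotation; truth masks follow the same geometry.
#'
#' @param spec a [phantom_spec].
#' @return a list with `record` (a [radiograph_record]) and `truth`: `text_mask`
#'   and `lung_mask` (logical matrices in the final rotated frame),
#'   `crop_box` (content box in the unrotated frame, 0-based half-open),
#'   `rotation` and `projection`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nr <- spec$size[1]; nc <- spec$size[2]

  anat <- .phantom_anatomy(spec$projection, nr, nc, spec$anatomy_jitter)
  img <- clamp01(anat$image^spec$gamma + spec$offset)
  lung <- anat$lung

  text_mask <- matrix(FALSE, nr, nc)
  for (item in spec$text_items) {
    scale <- as.integer(item$scale %||% 2L)
    pos <- .resolve_text_pos(item$pos %||% "tl", nr, nc, item$text, scale)
    tm <- render_text_mask(nr, nc, item$text, pos[1], pos[2], scale)
    img[tm] <- item$intensity %||% 1.0
    text_mask <- text_mask | tm
  }

  if (spec$blur_sigma > 0) {
    img <- clamp01(EBImage::gblur(img, sigma = spec$blur_sigma))
  }
  if (spec$noise_sd > 0) {
    img <- clamp01(img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc))
  }

  cw <- spec$collim_widths; pw <- spec$pad_width
  img <- .pad_matrix(img, cw[1], cw[2], cw[3], cw[4], spec$collim_value)
  img <- .pad_matrix(img, pw, pw, pw, pw, 0)
  text_mask <- .pad_matrix(text_mask, cw[1] + pw, cw[2] + pw, cw[3] + pw, cw[4] + pw, FALSE)
  lung <- .pad_matrix(lung, cw[1] + pw, cw[2] + pw, cw[3] + pw, cw[4] + pw, FALSE)

  box <- crop_box(pw + cw[1], pw + cw[1] + nr, pw + cw[3], pw + cw[3] + nc)

  if (spec$rotation != 0L) {
    img <- rotate_image(img, spec$rotation)
    text_mask <- rotate_image(text_mask, spec$rotation)
    lung <- rotate_image(lung, spec$rotation)
  }

  hdr <- spec$header
  md <- metadata_record(
    patient_id = hdr$patient_id %||% "P0001",
    manufacturer = hdr$manufacturer %||% NA_character_,
    deviation_index = hdr$deviation_index %||% NA_real_,
    sex = hdr$sex %||% NA_character_,
    age = hdr$age %||% NA,
    ethnicity = hdr$ethnicity %||% NA_character_,
    series_description = hdr$series_description %||% NA_character_,
    photometric = hdr$photometric %||% "MONOCHROME2",
    bits_stored = hdr$bits_stored %||% 12L
  )
  rec <- radiograph_record(img, md, source = sprintf("phantom:%d", spec$seed))
  rec <- record_log(rec, sprintf("generated:%s:seed=%d", spec$projection, spec$seed))
  list(record = rec,
       truth = list(text_mask = text_mask, lung_mask = lung, crop_box = box,
                    rotation = spec$rotation, projection = spec$projection))
}

#' Default distribution settings for synthetic datasets
#'
#' The marginals from which [generate_dataset] samples phantom specs:
#' class balance, how often burned-in text appears and how strongly its
#' token correlates with the projection, border/rotation/blur/noise rates,
#' the manufacturer mix with distinct gamma/offset transforms, header
#' completeness, and the rate at which Series Description carries a
#' projection token.
#'
#' @param ... overrides of the defaults.
#' @return a named list of distribution settings.
#' @export
dataset_config <- function(...) {
  cfg <- list(
    size = c(192L, 192L),
    frontal_prob = 0.5,
    text_prob = 0.9,
    text_rho = 1.0,              # P(token matches projection | text present)
    text_intensity = 1.0,
    text_scale = 2L,
    pad_prob = 0.6, pad_range = c(4L, 14L),
    collim_prob = 0.5, collim_range = c(6L, 18L), collim_value = 0.02,
    rotation_prob = 0,
    blur_prob = 0.1, blur_range = c(0.5, 1.5),
    noise_range = c(0.005, 0.02),
    anatomy_jitter = 0.1,
    manufacturers = list(
      # gamma/offset model the vendor-specific intensity transform; each
      # device also declares a display window derived from its own output:
      # centred on the data midrange, width = window_factor x the data range
      # (display windows cover the data span with vendor-specific headroom)
      list(name = "VendorA", gamma = 1.0, offset = 0.00, prob = 0.40,
           window_factor = 1.25),
      list(name = "VendorB", gamma = 1.6, offset = 0.06, prob = 0.35,
           window_factor = 1.50),
      list(name = "VendorC", gamma = 0.7, offset = -0.04, prob = 0.25,
           window_factor = 1.35)
    ),
    missing_rate = 0.05,          # P(one metadata field missing per image)
    multi_image_rate = 0.15,      # P(an image shares a patient with another)
    age_range_rate = 0.15,        # P(age is given as a decade range string)
    series_token_rate = 0.6,      # P(Series Description names a projection)
    series_wrong_rate = 0.03      # P(that token contradicts the projection)
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Generate a synthetic dataset with truth and curation table
#'
#' Samples [phantom_spec]s from the configured marginals, generates the
#' phantoms, and assembles the per-image curation table from the headers.
#' With `out_dir` set, writes DICOM files under `dicom/`, truth masks (PNG)
#' and truth JSON under `truth/`, and `curation.csv`.
#'
#' @param n number of images.
#' @param config a [dataset_config] list.
#' @param seed integer master seed; the dataset is deterministic given it.
#' @param out_dir optional output directory.
#' @return a list with `items` (each with `record`, `truth`, `spec`) and
#'   `curation` (data frame).
#' @export
generate_dataset <- function(n, config = dataset_config(), seed = 1L,
                             out_dir = NULL) {
  stopifnot(n >= 1L)
  set.seed(seed)
  mprob <- vapply(config$manufacturers, `[[`, numeric(1), "prob")
  mnames <- vapply(config$manufacturers, `[[`, character(1), "name")

  n_patients <- max(1L, round(n * (1 - config$multi_image_rate)))
  patient_pool <- sprintf("PAT%05d", seq_len(n_patients))
  patient_ids <- c(patient_pool,
                   sample(patient_pool, max(0L, n - n_patients), replace = TRUE))
  patient_ids <- sample(patient_ids, n)

  seeds <- sample.int(2147483646L, n)
  sexes <- sample(c("M", "F"), n, replace = TRUE)
  ethnicities <- sample(c("White", "Black", "Asian", "Other"), n, replace = TRUE,
                        prob = c(0.5, 0.2, 0.2, 0.1))

  items <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    frontal <- stats::runif(1) < config$frontal_prob
    projection <- if (frontal) "frontal" else "lateral"
    mi <- sample.int(length(mnames), 1L, prob = mprob)
    man <- config$manufacturers[[mi]]

    text_items <- list()
    token <- NA_character_
    if (stats::runif(1) < config$text_prob) {
      matches <- stats::runif(1) < config$text_rho
      tok_proj <- if (matches) projection else setdiff(c("frontal", "lateral"), projection)
      token <- if (tok_proj == "frontal") {
        sample(c("PA", "AP"), 1L)
      } else {
        sample(c("LAT", "LL"), 1L)
      }
      text_items <- list(list(text = token, pos = sample(c("tl", "tr"), 1L),
                              intensity = config$text_intensity,
                              scale = config$text_scale))
    }

    pad <- if (stats::runif(1) < config$pad_prob) {
      sample(config$pad_range[1]:config$pad_range[2], 1L)
    } else 0L
    collim <- if (stats::runif(1) < config$collim_prob) {
      sample(config$collim_range[1]:config$collim_range[2], 4L, replace = TRUE)
    } else c(0L, 0L, 0L, 0L)
    rot <- if (stats::runif(1) < config$rotation_prob) {
      sample(c(90L, 180L, 270L), 1L)
    } else 0L
    blur <- if (stats::runif(1) < config$blur_prob) {
      stats::runif(1, config$blur_range[1], config$blur_range[2])
    } else 0
    noise <- stats::runif(1, config$noise_range[1], config$noise_range[2])

    age <- if (stats::runif(1) < config$age_range_rate) {
      lo <- sample(2:8, 1L) * 10L
      sprintf("%d-%d", lo, lo + 9L)
    } else {
      round(stats::runif(1, 20, 90))
    }
    sd_text <- if (stats::runif(1) < config$series_token_rate) {
      wrong <- stats::runif(1) < config$series_wrong_rate
      sd_proj <- if (wrong) setdiff(c("frontal", "lateral"), projection) else projection
      if (sd_proj == "frontal") {
        sample(c("CHEST PA", "CHEST AP ERECT"), 1L)
      } else {
        sample(c("CHEST LATERAL", "CHEST LAT"), 1L)
      }
    } else "XR CHEST"

    header <- list(
      patient_id = patient_ids[i],
      manufacturer = man$name,
      deviation_index = round(stats::rnorm(1, 0, 1.5), 2),
      sex = sexes[i],
      age = age,
      ethnicity = ethnicities[i],
      series_description = sd_text,
      photometric = if (stats::runif(1) < 0.15) "MONOCHROME1" else "MONOCHROME2",
      bits_stored = sample(c(8L, 12L, 16L), 1L, prob = c(0.15, 0.5, 0.35))
    )
    if (stats::runif(1) < config$missing_rate) {
      field <- sample(c("manufacturer", "deviation_index", "sex", "age",
                        "ethnicity"), 1L)
      header[[field]] <- if (field %in% c("deviation_index")) NA_real_ else NA
    }

    spec <- phantom_spec(
      projection = projection, size = config$size, text_items = text_items,
      pad_width = pad, collim_widths = collim,
      collim_value = config$collim_value, rotation = rot,
      blur_sigma = blur, noise_sd = noise,
      gamma = man$gamma, offset = man$offset,
      anatomy_jitter = config$anatomy_jitter,
      header = header, seed = seeds[i]
    )
    ph <- generate_phantom(spec)
    content <- ph$record$image[ph$record$image > 0]
    if (length(content) && diff(range(content)) > 0) {
      rng <- range(content)
      attr(ph$record, "window") <- list(
        center = mean(rng),
        width = (man$window_factor %||% 1.25) * diff(rng))
    }
    items[[i]] <- list(record = ph$record, truth = ph$truth, spec = spec,
                       image_id = sprintf("IMG%05d", i), token = token)
    h <- header
    rows[[i]] <- data.frame(
      image_id = sprintf("IMG%05d", i),
      patient_id = h$patient_id,
      manufacturer = if (is_missing_field(h$manufacturer)) NA_character_ else h$manufacturer,
      deviation_index = if (is_missing_field(h$deviation_index)) NA_real_ else h$deviation_index,
      sex = if (is_missing_field(h$sex)) NA_character_ else h$sex,
      age = if (is_missing_field(h$age)) NA_character_ else as.character(h$age),
      ethnicity = if (is_missing_field(h$ethnicity)) NA_character_ else h$ethnicity,
      series_description = h$series_description,
      projection = projection,
      stringsAsFactors = FALSE
    )
  }
  curation <- do.call(rbind, rows)

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "dicom"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "truth"), recursive = TRUE, showWarnings = FALSE)
    for (it in items) {
      write_radiograph(it$record, file.path(out_dir, "dicom",
                                            paste0(it$image_id, ".dcm")),
                       window = attr(it$record, "window"))
      png::writePNG(it$truth$text_mask * 1,
                    file.path(out_dir, "truth", paste0(it$image_id, "_text.png")))
      jsonlite::write_json(
        list(crop_box = unclass(it$truth$crop_box),
             rotation = it$truth$rotation,
             projection = it$truth$projection),
        file.path(out_dir, "truth", paste0(it$image_id, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
    utils::write.csv(curation, file.path(out_dir, "curation.csv"),
                     row.names = FALSE)
  }
  invisible(list(items = items, curation = curation))
}
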
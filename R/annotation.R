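#' Detect burned-in text annotations
#'
#' Rule-based detector for burned-in laterality/technique markers. Candidate
#' pixels must be locally bright in the white top-hat sense (image minus its
#' morphological opening), which isolates thin stroke-like structures and
#' suppresses broad bright anatomy (mediastinum, spine, abdomen) even where
#' windowing has saturated it: a pixel is a candidate when it is either
#' near-saturated with some local prominence, or strongly prominent
#' regardless of absolute level (catching blurred text over dark
#' background). Candidates are grouped into connected components and kept
#' only when their geometry is text-like — component height within a
#' configured fraction of the image height, a stroke-like (non-solid) fill
#' ratio, and bounded width. Solid bright disks (jewelry, electrodes) have
#' no top-hat response and are never candidates. Retained components are
#' dilated by a safety margin.
#'
#' @param image numeric matrix in `[0, 1]`, standardised and cropped.
#' @param intensity_thresh near-saturation intensity for the first candidate
#'   rule.
#' @param tophat_soft minimum top-hat prominence accompanying
#'   `intensity_thresh`.
#' @param tophat_hard top-hat prominence that alone qualifies a pixel.
#' @param tophat_brush diameter (pixels) of the disc structuring element for
#'   the opening; must exceed twice the annotation stroke width.
#' @param min_height_frac,max_height_frac allowed component height as a
#'   fraction of image height (default 1% to 10%).
#' @param max_fill_ratio maximum fraction of the component bounding box the
#'   component may fill (strokes are sparse; solid blobs are not).
#' @param max_width_frac maximum component width as a fraction of image
#'   width.
#' @param min_pixels minimum component size in pixels (speckle rejection).
#' @param dilate_px dilation margin applied to the final mask.
#' @return a list of class `annotation_mask` with `mask` (logical matrix)
#'   and `components` (data frame of kept bounding boxes).
#' @export
detect_annotations <- function(image, intensity_thresh = 0.95,
                               tophat_soft = 0.10, tophat_hard = 0.25,
                               tophat_brush = 7L,
                               min_height_frac = 0.01, max_height_frac = 0.10,
                               max_fill_ratio = 0.82, max_width_frac = 0.30,
                               min_pixels = 4L, dilate_px = 2L) {
  nr <- nrow(image); nc <- ncol(image)
  opened <- EBImage::opening(image, EBImage::makeBrush(tophat_brush, shape = "disc"))
  tophat <- image - opened
  # the opening is unreliable within a brush radius of the frame edge
  # (outside pixels are treated as dark); ignore prominence there
  b <- tophat_brush %/% 2L + 1L
  tophat[c(seq_len(b), (nr - b + 1L):nr), ] <- 0
  tophat[, c(seq_len(b), (nc - b + 1L):nc)] <- 0
  bin <- (image >= intensity_thresh & tophat >= tophat_soft) |
    tophat >= tophat_hard
  mask <- matrix(FALSE, nr, nc)
  comps <- data.frame(row_start = integer(), row_end = integer(),
                      col_start = integer(), col_end = integer(),
                      n_pixels = integer())
  if (any(bin)) {
    # label on a 1-px dilation so diagonally-touching strokes form one
    # component; geometry is still measured on the undilated pixels
    grown <- EBImage::dilate(matrix(as.numeric(bin), nr, nc),
                             EBImage::makeBrush(3L, shape = "box")) > 0
    lab <- EBImage::bwlabel(matrix(as.numeric(grown), nr, nc))
    lab[!bin] <- 0
    idx <- which(lab > 0)
    if (length(idx)) {
      labs <- lab[idx]
      rows <- ((idx - 1L) %% nr) + 1L
      cols <- ((idx - 1L) %/% nr) + 1L
      rmin <- tapply(rows, labs, min); rmax <- tapply(rows, labs, max)
      cmin <- tapply(cols, labs, min); cmax <- tapply(cols, labs, max)
      npix <- tapply(rows, labs, length)
      h <- rmax - rmin + 1L; w <- cmax - cmin + 1L
      fill <- npix / (h * w)
      keep <- npix >= min_pixels &
        h >= min_height_frac * nr & h <= max_height_frac * nr &
        w <= max_width_frac * nc &
        fill <= max_fill_ratio
      keep_labs <- as.integer(names(keep)[keep])
      if (length(keep_labs)) {
        mask[idx[labs %in% keep_labs]] <- TRUE
        if (dilate_px > 0L) {
          brush <- EBImage::makeBrush(2L * dilate_px + 1L, shape = "box")
          mask <- EBImage::dilate(matrix(as.numeric(mask), nr, nc), brush) > 0
        }
        kidx <- match(keep_labs, as.integer(names(rmin)))
        comps <- data.frame(row_start = as.integer(rmin[kidx]) - 1L,
                            row_end = as.integer(rmax[kidx]),
                            col_start = as.integer(cmin[kidx]) - 1L,
                            col_end = as.integer(cmax[kidx]),
                            n_pixels = as.integer(npix[kidx]))
      }
    }
  }
  structure(list(mask = mask, components = comps), class = "annotation_mask")
}

#' @keywords internal
as_mask_matrix <- function(mask) {
  if (inherits(mask, "annotation_mask")) mask$mask else mask
}

#' Inpaint masked regions
#'
#' Replaces masked pixels by values propagated inward from the mask
#' boundary: an initial distance-ordered (onion-peel) fill by neighbourhood
#' averaging, refined by iterating a discrete Laplace smoother to convergence
#' within each mask component's bounding box. Unmasked pixels are returned
#' bit-identical to the input. Linear intensity ramps are reconstructed
#' exactly in the limit because linear functions are harmonic.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param mask logical matrix or [detect_annotations] result; `TRUE` pixels
#'   are replaced.
#' @param max_mask_frac refuse to inpaint when the mask covers more than
#'   this fraction of the image (default 0.5); refusal signals a condition
#'   of class `radqc_inpaint_refused` which the pipeline converts into a
#'   `flag_for_review`.
#' @param max_iter,tol Laplace-smoothing iteration cap and convergence
#'   tolerance.
#' @return the inpainted matrix.
#' @export
inpaint <- function(image, mask, max_mask_frac = 0.5, max_iter = 500L,
                    tol = 1e-6) {
  m <- as_mask_matrix(mask)
  stopifnot(identical(dim(m), dim(image)))
  if (!any(m)) return(image)
  if (mean(m) > max_mask_frac) {
    stop(structure(class = c("radqc_inpaint_refused", "error", "condition"),
                   list(message = sprintf(
                          "mask covers %.1f%% of the image; inpainting refused",
                          100 * mean(m)),
                        call = sys.call())))
  }
  out <- image
  nr <- nrow(image); nc <- ncol(image)

  lab <- EBImage::bwlabel(matrix(as.numeric(m), nr, nc))
  nlab <- max(lab)
  for (k in seq_len(nlab)) {
    idx <- which(lab == k)
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    r0 <- max(1L, min(rows) - 2L); r1 <- min(nr, max(rows) + 2L)
    c0 <- max(1L, min(cols) - 2L); c1 <- min(nc, max(cols) + 2L)
    sub <- out[r0:r1, c0:c1, drop = FALSE]
    submask <- m[r0:r1, c0:c1, drop = FALSE] & (lab[r0:r1, c0:c1, drop = FALSE] == k)
    out[r0:r1, c0:c1] <- .inpaint_patch(sub, submask, max_iter, tol)
  }
  # guarantee: unmasked pixels bit-identical
  out[!m] <- image[!m]
  clamp01(out)
}

# neighbour means with edge replication, computed by shifting
.neighbour_sum4 <- function(x) {
  up <- rbind(x[1, , drop = FALSE], x[-nrow(x), , drop = FALSE])
  dn <- rbind(x[-1, , drop = FALSE], x[nrow(x), , drop = FALSE])
  lf <- cbind(x[, 1, drop = FALSE], x[, -ncol(x), drop = FALSE])
  rt <- cbind(x[, -1, drop = FALSE], x[, ncol(x), drop = FALSE])
  up + dn + lf + rt
}

.inpaint_patch <- function(patch, pmask, max_iter, tol) {
  # onion-peel initial fill: repeatedly fill unknown pixels that have at
  # least one known 4/8-neighbour with the mean of their known neighbours
  known <- !pmask
  vals <- patch
  vals[pmask] <- 0
  while (!all(known)) {
    kn <- known * 1
    ksum <- .neighbour_sum4(vals * kn)
    kcnt <- .neighbour_sum4(kn)
    frontier <- !known & kcnt > 0
    if (!any(frontier)) break  # isolated region (cannot happen with bbox pad)
    vals[frontier] <- ksum[frontier] / kcnt[frontier]
    known <- known | frontier
  }
  # harmonic refinement inside the mask
  for (i in seq_len(max_iter)) {
    new <- .neighbour_sum4(vals) / 4
    delta <- max(abs(new[pmask] - vals[pmask]))
    vals[pmask] <- new[pmask]
    if (delta < tol) break
  }
  vals
}

#' Categorise an annotation-removal outcome
#'
#' Compares a predicted annotation mask with the ground-truth mask:
#' `none_present` when the truth is empty, otherwise the fraction of truth
#' pixels covered classifies the removal as `complete` (>= 0.99), `failed`
#' (<= 0.01) or `partial`. Inappropriate inpainting inside the lung field is
#' flagged when predicted pixels fall in the lung region without being true
#' annotation pixels.
#'
#' @param pred_mask predicted mask (logical matrix or `annotation_mask`).
#' @param truth_mask ground-truth annotation mask.
#' @param lung_region logical matrix marking the lung field (optional;
#'   `NULL` disables the in-lung check).
#' @return a list with `category`, `fraction_removed` and
#'   `inpainted_in_lung`.
#' @export
removal_outcome <- function(pred_mask, truth_mask, lung_region = NULL) {
  p <- as_mask_matrix(pred_mask); t <- as_mask_matrix(truth_mask)
  if (!identical(dim(p), dim(t))) stop("mask shapes disagree")
  if (!is.null(lung_region) && !identical(dim(lung_region), dim(t))) {
    stop("lung region shape disagrees with masks")
  }
  in_lung <- if (is.null(lung_region)) FALSE else any(p & lung_region & !t)
  if (!any(t)) {
    return(list(category = "none_present", fraction_removed = NA_real_,
                inpainted_in_lung = in_lung))
  }
  frac <- sum(p & t) / sum(t)
  category <- if (frac >= 0.99) "complete" else if (frac <= 0.01) "failed" else "partial"
  list(category = category, fraction_removed = frac, inpainted_in_lung = in_lung)
}
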
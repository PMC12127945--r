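#' Crop box (0-based, half-open)
#'
#' @param row_start,row_end,col_start,col_end integers, 0-based half-open
#'   bounds with `row_start < row_end` and `col_start < col_end`.
#' @return an object of class `crop_box`.
#' @export
crop_box <- function(row_start, row_end, col_start, col_end) {
  stopifnot(row_start >= 0, row_start < row_end, col_start >= 0,
            col_start < col_end)
  structure(list(row_start = as.integer(row_start), row_end = as.integer(row_end),
                 col_start = as.integer(col_start), col_end = as.integer(col_end)),
            class = "crop_box")
}

#' Apply a crop box to an image
#' @param image numeric matrix.
#' @param box a [crop_box] (0-based half-open coordinates).
#' @return the cropped matrix.
#' @export
crop_image <- function(image, box) {
  image[(box$row_start + 1L):box$row_end, (box$col_start + 1L):box$col_end,
        drop = FALSE]
}

#' Detect padding and collimation borders
#'
#' Finds the content box of a radiograph by stripping, from each side,
#' (a) border rows/columns that are constant to within `pad_tol`
#' (detector padding), then (b) contiguous near-black border bands whose
#' row/column mean lies at or below the `collim_quantile` quantile of the
#' remaining intensity distribution (collimation shadow). The total amount
#' stripped per dimension is capped at 45% so that anatomy can never be
#' cropped away wholesale.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param pad_tol max-minus-min tolerance for a line to count as constant
#'   padding (default 1/1024).
#' @param collim_quantile quantile of the padding-stripped intensity
#'   distribution used as the near-black threshold (default 0.05).
#' @param max_crop_frac per-dimension safety cap on the total stripped
#'   fraction (default 0.45).
#' @return a [crop_box] covering the content, or `NULL` when the whole image
#'   is classified as border (empty content).
#' @export
detect_border_crop <- function(image, pad_tol = 1 / 1024,
                               collim_quantile = 0.05,
                               max_crop_frac = 0.45) {
  nr <- nrow(image); nc <- ncol(image)
  max_r <- floor(max_crop_frac * nr)
  max_c <- floor(max_crop_frac * nc)
  top <- 0L; bottom <- 0L; left <- 0L; right <- 0L

  line_const <- function(v) (max(v) - min(v)) <= pad_tol
  sub <- function() image[(top + 1L):(nr - bottom), (left + 1L):(nc - right),
                          drop = FALSE]

  # pass 1: iteratively strip exact-constant border lines from all four sides
  repeat {
    changed <- FALSE
    s <- sub()
    if (nrow(s) > 1L && top + bottom < max_r && line_const(s[1L, ])) {
      top <- top + 1L; changed <- TRUE
    }
    s <- sub()
    if (nrow(s) > 1L && top + bottom < max_r && line_const(s[nrow(s), ])) {
      bottom <- bottom + 1L; changed <- TRUE
    }
    s <- sub()
    if (ncol(s) > 1L && left + right < max_c && line_const(s[, 1L])) {
      left <- left + 1L; changed <- TRUE
    }
    s <- sub()
    if (ncol(s) > 1L && left + right < max_c && line_const(s[, ncol(s)])) {
      right <- right + 1L; changed <- TRUE
    }
    if (!changed) break
  }
  s <- sub()
  if (max(s) - min(s) <= pad_tol) return(NULL)  # whole image is border

  # pass 2: strip contiguous near-black bands (collimation) from each side
  thr <- stats::quantile(s, probs = collim_quantile, names = FALSE, type = 7)
  rm_mean <- rowMeans(s); cm_mean <- colMeans(s)
  eps <- 1e-9
  i <- 1L
  while (i < length(rm_mean) && rm_mean[i] <= thr + eps && top + bottom < max_r) {
    top <- top + 1L; i <- i + 1L
  }
  i <- length(rm_mean)
  while (i > 1L && rm_mean[i] <= thr + eps && top + bottom < max_r) {
    bottom <- bottom + 1L; i <- i - 1L
  }
  j <- 1L
  while (j < length(cm_mean) && cm_mean[j] <= thr + eps && left + right < max_c) {
    left <- left + 1L; j <- j + 1L
  }
  j <- length(cm_mean)
  while (j > 1L && cm_mean[j] <= thr + eps && left + right < max_c) {
    right <- right + 1L; j <- j - 1L
  }
  if (top + bottom >= nr || left + right >= nc) return(NULL)
  crop_box(top, nr - bottom, left, nc - right)
}

# Orientation score: upright chest radiographs are (approximately) mirror
# symmetric about the vertical axis and bottom-heavy (the abdomen and
# diaphragm are radiodense, the apices are not). Both cues survive lateral
# projections well enough for 90-degree disambiguation.
#' @keywords internal
orientation_score <- function(image) {
  ds <- downsample_mean(image, 32L, 32L)
  third <- 32L %/% 3L
  bottom_heavy <- mean(ds[(32L - third + 1L):32L, ]) - mean(ds[1:third, ])
  bottom_heavy + 0.5 * mirror_symmetry(image)
}

#' Correct 90-degree rotations
#'
#' Scores the four axis-aligned orientations of an image and returns the one
#' that looks most upright, preferring 0, then 90, 180, 270 on ties. The
#' score combines vertical-axis mirror symmetry with top-versus-bottom
#' intensity asymmetry (in the canonical polarity the abdomen is brighter
#' than the apices).
#'
#' @param image numeric matrix (already cropped).
#' @return a list with `image` (the rotated matrix) and `rotation` (the
#'   clockwise rotation applied, one of 0, 90, 180, 270).
#' @export
correct_rotation <- function(image) {
  candidates <- c(0L, 90L, 180L, 270L)
  best <- 1L
  best_score <- -Inf
  rotated <- vector("list", 4L)
  for (k in seq_along(candidates)) {
    rotated[[k]] <- rotate_image(image, candidates[k])
    sc <- orientation_score(rotated[[k]])
    if (sc > best_score + 1e-12) {
      best <- k; best_score <- sc
    }
  }
  list(image = rotated[[best]], rotation = candidates[best])
}

#' Aspect-ratio screen
#'
#' Computes the width/height ratio (`ncols/nrows`) of a cropped image and
#' flags it for review when outside the configured bounds. The default
#' bounds of 0.85 and 1.48 are inclusive at both ends.
#'
#' @param image numeric matrix (already cropped).
#' @param lower,upper inclusive bounds on `ncols/nrows`.
#' @return a [qc_result] with stage `"aspect_ratio"`, action `pass` or
#'   `flag_for_review`, and the ratio as evidence.
#' @export
aspect_ratio_check <- function(image, lower = 0.85, upper = 1.48) {
  stopifnot(lower > 0, lower < upper)
  ratio <- ncol(image) / nrow(image)
  if (ratio >= lower && ratio <= upper) {
    qc_result("aspect_ratio", "pass", evidence = list(aspect_ratio = ratio))
  } else {
    qc_result("aspect_ratio", "flag_for_review", reasons = "aspect_ratio",
              evidence = list(aspect_ratio = ratio))
  }
}
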
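# clamps to [0, 1] preserving dim attributes
#' @keywords internal
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Rotate an image by a multiple of 90 degrees
#'
#' Rotates a matrix clockwise by 0, 90, 180 or 270 degrees. Used both by the
#' phantom generator (to inject mis-oriented images) and by the rotation
#' corrector (to undo them).
#'
#' @param image numeric matrix.
#' @param degrees one of 0, 90, 180, 270 (clockwise).
#' @return the rotated matrix.
#' @export
rotate_image <- function(image, degrees) {
  degrees <- as.integer(degrees) %% 360L
  if (!degrees %in% c(0L, 90L, 180L, 270L)) {
    stop("degrees must be a multiple of 90")
  }
  out <- image
  k <- degrees %/% 90L
  for (i in seq_len(k)) {
    # one clockwise quarter turn
    out <- t(out)[, nrow(out):1, drop = FALSE]
  }
  out
}

# Block-mean downsampling to a fixed grid. Each output cell is the mean of
# the input pixels whose (scaled) coordinates fall in it, so the result is
# deterministic and invariant to the exact input resolution.
#' @keywords internal
downsample_mean <- function(image, nrow_out = 32L, ncol_out = 32L) {
  nr <- nrow(image); nc <- ncol(image)
  ri <- pmin(nrow_out, floor((seq_len(nr) - 1) * nrow_out / nr) + 1L)
  ci <- pmin(ncol_out, floor((seq_len(nc) - 1) * ncol_out / nc) + 1L)
  byrow <- rowsum(image, group = ri, reorder = TRUE)
  byboth <- t(rowsum(t(byrow), group = ci, reorder = TRUE))
  counts <- outer(tabulate(ri, nrow_out), tabulate(ci, ncol_out))
  byboth / counts
}

# Mirror about the vertical axis (left-right flip).
#' @keywords internal
fliplr <- function(image) image[, ncol(image):1, drop = FALSE]

# Vertical-axis mirror symmetry in [0, 1]; 1 means perfectly symmetric.
# Normalised by overall image variability so it is contrast-invariant.
#' @keywords internal
mirror_symmetry <- function(image, grid = 32L) {
  ds <- downsample_mean(image, grid, grid)
  spread <- mean(abs(ds - mean(ds)))
  if (spread < 1e-12) return(1)
  1 - mean(abs(ds - fliplr(ds))) / (2 * spread)
}

#' @keywords internal
is_missing_field <- function(x) {
  is.null(x) || length(x) == 0L || all(is.na(x)) ||
    (is.character(x) && !any(nzchar(trimws(x))))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
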
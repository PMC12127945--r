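#' Linear VOI windowing
#'
#' Applies the value-of-interest transform that standardises pixel
#' intensities across vendors: values at or below `center - width/2` map to
#' 0, values at or above `center + width/2` map to 1, with a linear ramp in
#' between. When no window is supplied, an automatic window is computed from
#' the 1st and 99th percentiles of the non-padding (non-zero) pixels, so
#' constant zero padding is preserved at 0 while the anatomy is stretched to
#' span `[0, 1]`.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param center,width window parameters in `[0, 1]` units; both `NA` (the
#'   default) selects the percentile auto-window.
#' @param probs percentiles used by the auto-window.
#' @return windowed matrix in `[0, 1]`, monotone non-decreasing in the input.
#' @export
apply_windowing <- function(image, center = NA_real_, width = NA_real_,
                            probs = c(0.01, 0.99)) {
  if (!is.na(width) && width <= 0) stop("window width must be positive")
  if (is.na(center) || is.na(width)) {
    content <- image[image > 0]
    if (length(content) < 2L) return(image)
    q <- stats::quantile(content, probs = probs, names = FALSE, type = 7)
    center <- (q[1] + q[2]) / 2
    width <- max(q[2] - q[1], 1e-6)
  }
  lo <- center - width / 2
  clamp01((image - lo) / width)
}

#' Summary statistics used to monitor intensity harmonization
#'
#' Mean, standard deviation, coefficient of variation and Shannon histogram
#' entropy of an image. After LUT/window standardisation these statistics are
#' expected to decrease on a heterogeneous multi-vendor dataset, and the
#' standardized mean difference between manufacturers to shrink.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param nbins number of equal-width histogram bins on `[0, 1]` for the
#'   entropy (default 256, giving a maximum entropy of 8 bits).
#' @return a list with elements `mean`, `sd`, `cv` and `entropy` (bits).
#'   `cv` is `NA` when the mean is 0 but the sd is not; a constant image has
#'   sd 0, cv 0 and entropy 0.
#' @export
intensity_stats <- function(image, nbins = 256L) {
  stopifnot(length(image) > 0L)
  m <- mean(image)
  s <- stats::sd(as.vector(image))
  if (is.na(s)) s <- 0
  cv <- if (s == 0) 0 else if (m == 0) NA_real_ else s / m
  bins <- pmin(nbins, floor(as.vector(image) * nbins) + 1L)
  p <- tabulate(bins, nbins) / length(image)
  p <- p[p > 0]
  list(mean = m, sd = s, cv = cv, entropy = -sum(p * log2(p)))
}

#' Standardized mean difference between two groups
#'
#' `|mean_a - mean_b| / sqrt((sd_a^2 + sd_b^2) / 2)` (unweighted two-group
#' pooling). Used to quantify how far apart two manufacturers' intensity
#' statistics sit, before and after windowing.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return a non-negative number; 0 when both pooled sd and the mean
#'   difference are 0, `Inf` when the pooled sd is 0 but the means differ.
#' @export
standardized_mean_difference <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  pooled <- sqrt((stats::var(values_a) + stats::var(values_b)) / 2)
  dm <- abs(mean(values_a) - mean(values_b))
  if (pooled == 0) {
    if (dm == 0) return(0)
    return(Inf)
  }
  dm / pooled
}
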
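#' Binary classification metrics
#'
#' The seven evaluation metrics: AUROC, accuracy, precision (positive
#' predictive value), recall (sensitivity), specificity, negative predictive
#' value and F1. AUROC is the rank statistic (Mann-Whitney with ties
#' averaged). Undefined metrics (division by zero, or AUROC with a single
#' class) are `NA`, never silently propagated NaN.
#'
#' @param y_true 0/1 (or logical) vector of true labels.
#' @param y_pred 0/1 (or logical) vector of predicted labels.
#' @param y_score numeric scores for the positive class (used for AUROC);
#'   optional.
#' @return named numeric vector with elements `auroc`, `accuracy`,
#'   `precision`, `recall`, `specificity`, `npv`, `f1`.
#' @export
classification_metrics <- function(y_true, y_pred, y_score = NULL) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  tp <- sum(y_true == 1L & y_pred == 1L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  # direct confusion-matrix form: defined (possibly 0) whenever any
  # positive exists in truth or prediction
  f1 <- div(2 * tp, 2 * tp + fp + fn)
  auroc <- NA_real_
  if (!is.null(y_score)) {
    n1 <- sum(y_true == 1L); n0 <- sum(y_true == 0L)
    if (n1 > 0L && n0 > 0L) {
      r <- rank(y_score)
      auroc <- (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  c(auroc = auroc,
    accuracy = div(tp + tn, length(y_true)),
    precision = precision,
    recall = recall,
    specificity = div(tn, tn + fp),
    npv = div(tn, tn + fn),
    f1 = f1)
}

#' Bootstrap confidence intervals for classification metrics
#'
#' Percentile bootstrap over case resamples: `n_boot` seeded resamples with
#' replacement of the test indices, 2.5/97.5 percentile intervals. Resamples
#' containing a single class contribute no AUROC value; their count is
#' reported.
#'
#' @param y_true,y_pred,y_score as in [classification_metrics].
#' @param n_boot number of resamples (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return data frame with columns `metric`, `estimate`, `ci_low`,
#'   `ci_high`; attribute `n_auroc_skipped` counts single-class resamples.
#' @export
bootstrap_ci <- function(y_true, y_pred, y_score = NULL, n_boot = 1000L,
                         seed = 1L, conf = 0.95) {
  stopifnot(n_boot >= 1L)
  point <- classification_metrics(y_true, y_pred, y_score)
  set.seed(seed)
  n <- length(y_true)
  boot <- matrix(NA_real_, nrow = n_boot, ncol = length(point),
                 dimnames = list(NULL, names(point)))
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    ix <- sample.int(n, n, replace = TRUE)
    if (length(unique(y_true[ix])) < 2L) skipped <- skipped + 1L
    boot[b, ] <- classification_metrics(y_true[ix], y_pred[ix],
                                        if (is.null(y_score)) NULL else y_score[ix])
  }
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 2L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(c(NA_real_, NA_real_))
    stats::quantile(col, probs = c(alpha, 1 - alpha), names = FALSE, type = 7)
  })
  out <- data.frame(metric = names(point), estimate = unname(point),
                    ci_low = ci[1L, ], ci_high = ci[2L, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_auroc_skipped") <- skipped
  out
}

#' Intersection over union of two masks
#'
#' Jaccard index `|A&B| / |A|B|`; two empty masks have IoU 1 by convention
#' (nothing to find, nothing found).
#'
#' @param mask_a,mask_b logical matrices of equal shape.
#' @return number in `[0, 1]`.
#' @export
mask_iou <- function(mask_a, mask_b) {
  a <- as_mask_matrix(mask_a); b <- as_mask_matrix(mask_b)
  if (!identical(dim(a), dim(b))) stop("mask shapes disagree")
  uni <- sum(a | b)
  if (uni == 0L) return(1)
  sum(a & b) / uni
}

#' Occlusion-sensitivity saliency map
#'
#' Model-agnostic attribution: each patch of the image is replaced by the
#' image mean and the magnitude of the resulting score change recorded,
#' normalised to `[0, 1]` over the patch grid. Stands in for
#' gradient-weighted class-activation maps for models without gradients.
#'
#' @param model a `projection_model` (or any object accepted by `score_fn`).
#' @param image image matrix.
#' @param patch,stride patch size and stride in pixels (`patch >= stride >= 1`).
#' @param score_fn function `(model, image) -> numeric score`; the default
#'   uses the frontal probability of a `projection_model`.
#' @return numeric matrix over the patch grid with values in `[0, 1]`, with
#'   attribute `image_dim` recording the input size.
#' @export
saliency_map <- function(model, image, patch = 24L, stride = 24L,
                         score_fn = NULL) {
  stopifnot(patch >= stride, stride >= 1L)
  if (is.null(score_fn)) {
    score_fn <- function(m, img) project_score(m, extract_projection_features(img))
  }
  base <- score_fn(model, image)
  fill <- mean(image)
  r_starts <- seq(1L, max(1L, nrow(image) - patch + 1L), by = stride)
  c_starts <- seq(1L, max(1L, ncol(image) - patch + 1L), by = stride)
  drops <- matrix(0, length(r_starts), length(c_starts))
  for (i in seq_along(r_starts)) {
    for (j in seq_along(c_starts)) {
      occ <- image
      rr <- r_starts[i]:min(nrow(image), r_starts[i] + patch - 1L)
      cc <- c_starts[j]:min(ncol(image), c_starts[j] + patch - 1L)
      occ[rr, cc] <- fill
      drops[i, j] <- abs(base - score_fn(model, occ))
    }
  }
  mx <- max(drops)
  if (mx > 0) drops <- drops / mx
  attr(drops, "image_dim") <- dim(image)
  attr(drops, "patch") <- patch
  attr(drops, "stride") <- stride
  drops
}

#' Binarise a saliency map to a pixel mask
#'
#' Grid cells above the given quantile of the map values become `TRUE` and
#' are expanded to their pixel footprint, for IoU against truth masks.
#'
#' @param map output of [saliency_map].
#' @param quantile binarisation quantile (default 0.9).
#' @return logical matrix at the original image size.
#' @export
saliency_mask <- function(map, quantile = 0.9) {
  dims <- attr(map, "image_dim")
  patch <- attr(map, "patch"); stride <- attr(map, "stride")
  thr <- stats::quantile(map, probs = quantile, names = FALSE, type = 7)
  out <- matrix(FALSE, dims[1], dims[2])
  r_starts <- seq(1L, max(1L, dims[1] - patch + 1L), by = stride)
  c_starts <- seq(1L, max(1L, dims[2] - patch + 1L), by = stride)
  for (i in seq_along(r_starts)) {
    for (j in seq_along(c_starts)) {
      if (map[i, j] > thr) {
        rr <- r_starts[i]:min(dims[1], r_starts[i] + patch - 1L)
        cc <- c_starts[j]:min(dims[2], c_starts[j] + patch - 1L)
        out[rr, cc] <- TRUE
      }
    }
  }
  out
}
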
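#' Engineered features for projection classification
#'
#' Fixed-length feature vector regardless of input resolution: the 32x32
#' block-mean downsampled intensities, a vertical-mirror-symmetry score
#' (frontal projections are approximately symmetric, laterals are not),
#' and low-order moments of the row and column intensity profiles.
#'
#' @param image numeric matrix in `[0, 1]`, standardised and cropped.
#' @return numeric vector of length 1030.
#' @export
extract_projection_features <- function(image) {
  ds <- downsample_mean(image, 32L, 32L)
  rp <- rowMeans(ds); cp <- colMeans(ds)
  wmoments <- function(p) {
    w <- p - min(p)
    s <- sum(w)
    if (s < 1e-12) return(c(0.5, 0))
    pos <- seq_along(p) / length(p)
    mu <- sum(pos * w) / s
    c(mu, sqrt(sum((pos - mu)^2 * w) / s))
  }
  third <- length(rp) %/% 3L
  tb_diff <- mean(rp[(length(rp) - third + 1L):length(rp)]) - mean(rp[1:third])
  c(as.vector(ds), mirror_symmetry(image), wmoments(rp), wmoments(cp), tb_diff)
}

.FEATURE_VERSION <- "radqc-feat-1"

#' Train the frontal-vs-lateral classifier
#'
#' Ridge-regularised logistic regression on [extract_projection_features].
#' Deterministic given the seed (the fit itself has no stochastic component;
#' the seed is recorded for provenance and any future stochastic backend).
#' The handle is a plain interface — any model exposing a frontal-probability
#' score over the same features can be swapped in.
#'
#' @param images list of image matrices, or a precomputed feature matrix
#'   (rows = images).
#' @param labels character or factor with levels `"frontal"` / `"lateral"`.
#' @param seed integer seed, recorded in the model handle.
#' @param lambda ridge penalty.
#' @param threshold frontal-probability decision threshold (default 0.5).
#' @return an object of class `projection_model`.
#' @export
train_projection_model <- function(images, labels, seed = 1L, lambda = 0.05,
                                   threshold = 0.5) {
  labels <- as.character(labels)
  if (!all(labels %in% c("frontal", "lateral"))) {
    stop("labels must be 'frontal' or 'lateral'")
  }
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (length(labels) < 50L) stop("need at least 50 labelled images")
  x <- if (is.matrix(images)) {
    images
  } else {
    do.call(rbind, lapply(images, extract_projection_features))
  }
  stopifnot(nrow(x) == length(labels))
  set.seed(seed)
  y <- as.integer(labels == "frontal")
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  structure(
    list(fit = fit, lambda = lambda, threshold = threshold,
         feature_version = .FEATURE_VERSION, n_features = ncol(x),
         seed = as.integer(seed)),
    class = "projection_model"
  )
}

#' Score of the frontal class for one or more feature rows
#' @keywords internal
project_score <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$n_features) {
    stop("feature length mismatch: model expects ", model$n_features)
  }
  as.numeric(stats::predict(model$fit, newx = x, s = model$lambda,
                            type = "response"))
}

#' Predict the projection of an image
#'
#' @param model a `projection_model`.
#' @param image image matrix preprocessed like the training images.
#' @param threshold optional override of the model's decision threshold.
#' @return a list of class `projection_call` with `label`
#'   (`"frontal"` iff `score >= threshold`), `score` (frontal probability)
#'   and `threshold_used`.
#' @export
predict_projection <- function(model, image, threshold = NULL) {
  stopifnot(inherits(model, "projection_model"))
  thr <- threshold %||% model$threshold
  score <- project_score(model, extract_projection_features(image))
  structure(list(label = if (score >= thr) "frontal" else "lateral",
                 score = score, threshold_used = thr),
            class = "projection_call")
}

#' Save / load a projection model
#'
#' The model file carries the feature-spec version, which is checked on
#' load so a model can never silently run on incompatible features.
#'
#' @param model a `projection_model`.
#' @param path file path.
#' @return `save_projection_model` returns the path invisibly;
#'   `load_projection_model` returns the model.
#' @export
save_projection_model <- function(model, path) {
  stopifnot(inherits(model, "projection_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_projection_model
#' @export
load_projection_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "projection_model") ||
      !identical(model$feature_version, .FEATURE_VERSION)) {
    stop("incompatible model file (feature version mismatch)")
  }
  model
}

#' Default projection token table
#'
#' Editable mapping from Series Description tokens to projections. Lateral
#' tokens take precedence when both kinds occur in the same header.
#'
#' @return list with `frontal` and `lateral` character vectors.
#' @export
projection_tokens <- function() {
  list(frontal = c("PA", "AP", "FRONTAL", "ERECT"),
       lateral = c("LAT", "LATERAL", "LL", "RL"))
}

#' Parse the projection declared in a Series Description
#'
#' Case-insensitive whole-token matching against the configured token
#' table. When both frontal and lateral tokens occur (e.g. "PA AND
#' LATERAL"), the lateral reading wins: such series usually bundle both
#' views and mislabelling a lateral as frontal is the costlier error.
#'
#' @param text Series Description string (or `NA`).
#' @param tokens token table as from [projection_tokens].
#' @return list with `declared` (`"frontal"`, `"lateral"` or `"absent"`)
#'   and `matched_token` (`NA` when absent).
#' @export
parse_series_description <- function(text, tokens = projection_tokens()) {
  if (is_missing_field(text)) {
    return(list(declared = "absent", matched_token = NA_character_))
  }
  words <- strsplit(toupper(text), "[^A-Z0-9]+")[[1]]
  lat <- intersect(words, tokens$lateral)
  if (length(lat)) {
    return(list(declared = "lateral", matched_token = lat[1]))
  }
  fro <- intersect(words, tokens$frontal)
  if (length(fro)) {
    return(list(declared = "frontal", matched_token = fro[1]))
  }
  list(declared = "absent", matched_token = NA_character_)
}

#' Check declared vs predicted projection
#'
#' @param declared result of [parse_series_description].
#' @param predicted a `projection_call` (or `NULL` when no model ran).
#' @return a [qc_result] with stage `"consistency"`: `pass` when the header
#'   is silent or agrees with the prediction, otherwise `flag_for_review`
#'   with reason `"metadata_mismatch"`.
#' @export
consistency_check <- function(declared, predicted) {
  evidence <- list()
  if (!is.null(predicted)) evidence$score <- predicted$score
  if (declared$declared == "absent" || is.null(predicted) ||
      declared$declared == predicted$label) {
    qc_result("consistency", "pass", evidence = evidence)
  } else {
    qc_result("consistency", "flag_for_review", reasons = "metadata_mismatch",
              evidence = evidence)
  }
}
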
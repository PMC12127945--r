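#' Default settings for the text-removal impact experiment
#'
#' The experiment emulates shortcut learning: burned-in laterality tokens
#' correlate perfectly with the image label (`text_rho = 1`), while the
#' anatomy is only an imperfect predictor — with probability
#' `1 - anatomy_rho` the image carries the opposite projection's anatomy
#' (emulating atypical or ambiguous anatomy) — and is further degraded by
#' jitter and noise. A model trained on the original images is therefore
#' tempted to read the text instead of the anatomy. Border and rotation
#' degradations are disabled: they are orthogonal to the question.
#'
#' @param ... overrides.
#' @return named list of experiment settings.
#' @export
shortcut_config <- function(...) {
  cfg <- list(
    n_train = 240L,            # total training images (balanced in expectation)
    n_test = 100L,
    size = c(192L, 192L),
    text_rho = 1.0,
    text_intensity = 1.0,
    anatomy_rho = 0.75,        # P(anatomy matches the label)
    anatomy_jitter = 0.45,
    noise_sd = c(0.01, 0.03),
    n_boot = 200L,
    n_saliency = 32L,
    saliency_patch = 24L,
    saliency_quantile = 0.9
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

# Generate n labelled phantoms for the experiment. The label drives the
# burned-in token (matching with probability text_rho); the anatomy matches
# the label only with probability anatomy_rho. All random draws happen
# before phantom generation because generate_phantom reseeds the RNG.
.shortcut_generate <- function(n, cfg, with_text, seed) {
  set.seed(seed)
  item_seeds <- sample.int(2147483646L, n)
  labels <- sample(c("frontal", "lateral"), n, replace = TRUE)
  anat_match <- stats::runif(n) < cfg$anatomy_rho
  tok_match <- stats::runif(n) < cfg$text_rho
  tok_pick <- stats::runif(n)
  pos_pick <- sample(c("tl", "tr"), n, replace = TRUE)
  noise <- stats::runif(n, cfg$noise_sd[1], cfg$noise_sd[2])
  lapply(seq_len(n), function(i) {
    label <- labels[i]
    anat <- if (anat_match[i]) label else setdiff(c("frontal", "lateral"), label)
    text_items <- list()
    if (with_text) {
      tok_proj <- if (tok_match[i]) label else setdiff(c("frontal", "lateral"), label)
      token <- if (tok_proj == "frontal") {
        if (tok_pick[i] < 0.5) "PA" else "AP"
      } else {
        if (tok_pick[i] < 0.5) "LAT" else "LL"
      }
      text_items <- list(list(text = token, pos = pos_pick[i],
                              intensity = cfg$text_intensity, scale = 2L))
    }
    sp <- phantom_spec(projection = anat, size = cfg$size,
                       text_items = text_items, noise_sd = noise[i],
                       anatomy_jitter = cfg$anatomy_jitter,
                       seed = item_seeds[i])
    ph <- generate_phantom(sp)
    ph$truth$projection <- label  # the label, not the (possibly swapped) anatomy
    list(record = ph$record, truth = ph$truth)
  })
}

# standardize + the three text-removal variants of one generated item
.shortcut_variants <- function(item) {
  img <- apply_windowing(item$record$image)
  truth <- item$truth$text_mask
  inpainted <- inpaint(img, detect_annotations(img))
  zero <- img
  if (any(truth)) {
    # zero-intensity bounding boxes around each truth component
    lab <- EBImage::bwlabel(matrix(as.numeric(truth), nrow(truth), ncol(truth)))
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k)
      rows <- ((idx - 1L) %% nrow(truth)) + 1L
      cols <- ((idx - 1L) %/% nrow(truth)) + 1L
      zero[min(rows):max(rows), min(cols):max(cols)] <- 0
    }
  }
  list(original = img, inpainted = inpainted, zero_box = zero, truth = truth,
       label = item$truth$projection)
}

#' Text-removal impact experiment
#'
#' Trains three frontal-projection models — on original images, on images
#' with annotations removed by detection + inpainting, and on images with
#' the annotation bounding boxes zeroed — in a regime where burned-in text
#' correlates perfectly with the projection. Each model is evaluated on
#' with-text, text-removed (inpainted) and never-annotated test variants,
#' and the mean saliency-mask IoU against the truth annotation masks is
#' computed per model, with paired-bootstrap difference intervals.
#'
#' @param config a [shortcut_config] list.
#' @param seed integer master seed.
#' @return list with `metrics` (data frame: model x test variant x the seven
#'   metrics), `accuracy` (3x3 matrix), `iou` (per-model mean IoU),
#'   `iou_diff` (paired bootstrap differences) and `config`.
#' @export
text_removal_experiment <- function(config = shortcut_config(), seed = 1L) {
  if (config$text_rho <= 0) {
    stop("degenerate config: no text-class correlation, the experiment ",
         "cannot probe shortcut learning")
  }
  set.seed(seed)
  seeds <- sample.int(2147483646L, 4L)

  train_raw <- .shortcut_generate(config$n_train, config, with_text = TRUE,
                                  seed = seeds[1])
  test_raw <- .shortcut_generate(config$n_test, config, with_text = TRUE,
                                 seed = seeds[2])
  clean_raw <- .shortcut_generate(config$n_test, config, with_text = FALSE,
                                  seed = seeds[3])

  train_v <- lapply(train_raw, .shortcut_variants)
  test_v <- lapply(test_raw, .shortcut_variants)
  clean_imgs <- lapply(clean_raw, function(it) apply_windowing(it$record$image))

  train_labels <- vapply(train_v, `[[`, character(1), "label")
  test_labels <- vapply(test_v, `[[`, character(1), "label")
  clean_labels <- vapply(clean_raw, function(it) it$truth$projection,
                         character(1))
  if (length(unique(train_labels)) < 2L) stop("training set lacks a class")

  feats <- function(imgs) do.call(rbind, lapply(imgs, extract_projection_features))
  models <- list(
    original = train_projection_model(feats(lapply(train_v, `[[`, "original")),
                                      train_labels, seed = seeds[4]),
    inpainted = train_projection_model(feats(lapply(train_v, `[[`, "inpainted")),
                                       train_labels, seed = seeds[4]),
    zero_box = train_projection_model(feats(lapply(train_v, `[[`, "zero_box")),
                                      train_labels, seed = seeds[4])
  )

  test_sets <- list(
    with_text = list(x = feats(lapply(test_v, `[[`, "original")), y = test_labels),
    text_removed = list(x = feats(lapply(test_v, `[[`, "inpainted")), y = test_labels),
    never_annotated = list(x = feats(clean_imgs), y = clean_labels)
  )

  rows <- list()
  accuracy <- matrix(NA_real_, 3L, 3L,
                     dimnames = list(names(models), names(test_sets)))
  for (mn in names(models)) {
    for (tn in names(test_sets)) {
      ts <- test_sets[[tn]]
      score <- project_score(models[[mn]], ts$x)
      y_true <- as.integer(ts$y == "frontal")
      y_pred <- as.integer(score >= models[[mn]]$threshold)
      ci <- bootstrap_ci(y_true, y_pred, score, n_boot = config$n_boot,
                         seed = seed)
      est <- stats::setNames(ci$estimate, ci$metric)
      accuracy[mn, tn] <- est[["accuracy"]]
      rows[[paste(mn, tn)]] <- data.frame(
        model = mn, test_variant = tn, metric = ci$metric,
        estimate = ci$estimate, ci_low = ci$ci_low, ci_high = ci$ci_high,
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  # saliency IoU on with-text test images with non-empty truth masks
  has_text <- which(vapply(test_v, function(v) any(v$truth), logical(1)))
  sal_ix <- has_text[seq_len(min(config$n_saliency, length(has_text)))]
  iou_mat <- matrix(NA_real_, length(sal_ix), 3L,
                    dimnames = list(NULL, names(models)))
  for (r in seq_along(sal_ix)) {
    v <- test_v[[sal_ix[r]]]
    for (mn in names(models)) {
      map <- saliency_map(models[[mn]], v$original,
                          patch = config$saliency_patch,
                          stride = config$saliency_patch)
      iou_mat[r, mn] <- mask_iou(saliency_mask(map, config$saliency_quantile),
                                 v$truth)
    }
  }
  iou <- data.frame(model = colnames(iou_mat), mean_iou = colMeans(iou_mat),
                    row.names = NULL, stringsAsFactors = FALSE)

  set.seed(seed + 1L)
  pairs <- utils::combn(names(models), 2L)
  iou_diff <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    deltas <- replicate(config$n_boot, {
      ix <- sample.int(nrow(iou_mat), nrow(iou_mat), replace = TRUE)
      mean(iou_mat[ix, a]) - mean(iou_mat[ix, b])
    })
    data.frame(model_a = a, model_b = b,
               delta = mean(iou_mat[, a]) - mean(iou_mat[, b]),
               ci_low = stats::quantile(deltas, 0.025, names = FALSE),
               ci_high = stats::quantile(deltas, 0.975, names = FALSE),
               stringsAsFactors = FALSE)
  }))

  list(metrics = metrics, accuracy = accuracy, iou = iou, iou_diff = iou_diff,
       iou_per_image = iou_mat, config = config)
}
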
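# Shared helpers for the radqc test suite.

# A small deterministic phantom, optionally with text, windowed the way the
# pipeline windows it.
make_phantom <- function(seed = 1L, text = NULL, ...) {
  text_items <- if (is.null(text)) list() else {
    list(list(text = text, pos = "tl", intensity = 1, scale = 2L))
  }
  generate_phantom(phantom_spec(seed = seed, text_items = text_items, ...))
}

windowed <- function(ph) apply_windowing(ph$record$image)

# Fast synthetic curation table with the same marginals the generator uses,
# but without building any images.
make_curation_table <- function(n, seed = 1L, missing_rate = 0) {
  set.seed(seed)
  tab <- data.frame(
    image_id = sprintf("IMG%05d", seq_len(n)),
    patient_id = sprintf("PAT%05d", seq_len(n)),
    manufacturer = sample(c("VendorA", "VendorB", "VendorC"), n, TRUE),
    deviation_index = round(stats::rnorm(n, 0, 1.5), 2),
    sex = sample(c("M", "F"), n, TRUE),
    age = as.character(sample(20:90, n, TRUE)),
    ethnicity = sample(c("White", "Black", "Asian", "Other"), n, TRUE),
    stringsAsFactors = FALSE)
  if (missing_rate > 0) {
    miss <- which(stats::runif(n) < missing_rate)
    for (i in miss) {
      f <- sample(c("manufacturer", "deviation_index", "sex", "age",
                    "ethnicity"), 1L)
      tab[[f]][i] <- NA
    }
  }
  tab
}

# Brute-force confusion-matrix oracle for the seven metrics.
metrics_oracle <- function(y, p, s) {
  tp <- sum(p == 1 & y == 1); tn <- sum(p == 0 & y == 0)
  fp <- sum(p == 1 & y == 0); fn <- sum(p == 0 & y == 1)
  auc <- if (sum(y == 1) == 0 || sum(y == 0) == 0) NaN else {
    mean(outer(s[y == 1], s[y == 0], function(a, b) (a > b) + 0.5 * (a == b)))
  }
  c(auroc = auc, accuracy = (tp + tn) / length(y),
    precision = tp / (tp + fp), recall = tp / (tp + fn),
    specificity = tn / (tn + fp), npv = tn / (tn + fn),
    f1 = 2 * tp / (2 * tp + fp + fn))
}

# Brute-force largest-remainder oracle.
lr_oracle <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- raw - base
  extra <- n - sum(base)
  ord <- order(-rem, seq_along(rem))
  if (extra > 0) base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  as.integer(base)
}
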
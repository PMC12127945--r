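test_that("classification metrics match the confusion-matrix oracle", {
  set.seed(61)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    y <- rbinom(n, 1, 0.5); if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(runif(n), 2)            # ties on purpose
    p <- as.integer(s >= 0.5)
    got <- classification_metrics(y, p, s)
    want <- metrics_oracle(y, p, s)
    for (k in names(want)) {
      if (is.nan(want[[k]])) {
        expect_true(is.na(got[[k]]))
      } else {
        expect_equal(got[[k]], want[[k]], tolerance = 1e-12)
      }
    }
  }
})

test_that("AUROC handles ties and degenerate classes", {
  expect_equal(unname(classification_metrics(c(1, 0), c(1, 0), c(0.5, 0.5))["auroc"]),
               0.5)
  expect_true(is.na(classification_metrics(c(1, 1), c(1, 1), c(0.9, 0.1))["auroc"]))
  expect_true(is.na(classification_metrics(c(1, 0), c(1, 0))["auroc"]))
})

test_that("bootstrap CIs contain point estimates and shrink with n", {
  set.seed(62)
  mk <- function(n) {
    y <- rbinom(n, 1, 0.5)
    s <- plogis(1.5 * (y - 0.5) + rnorm(n))
    list(y = y, s = s, p = as.integer(s >= 0.5))
  }
  small <- mk(60); big <- mk(1000)
  ci_s <- bootstrap_ci(small$y, small$p, small$s, n_boot = 300, seed = 1)
  ci_b <- bootstrap_ci(big$y, big$p, big$s, n_boot = 300, seed = 1)
  expect_equal(ci_b$metric,
               c("auroc", "accuracy", "precision", "recall", "specificity",
                 "npv", "f1"))
  ok <- ci_b$ci_low <= ci_b$estimate + 1e-12 &
    ci_b$estimate <= ci_b$ci_high + 1e-12
  expect_true(all(ok))
  expect_true(all((ci_b$ci_high - ci_b$ci_low) <
                    (ci_s$ci_high - ci_s$ci_low)))
  expect_gte(attr(ci_s, "n_auroc_skipped"), 0)
  # deterministic given the seed
  expect_identical(ci_s, bootstrap_ci(small$y, small$p, small$s,
                                      n_boot = 300, seed = 1))
})

test_that("mask IoU follows the documented conventions", {
  a <- matrix(FALSE, 4, 4); b <- a
  expect_equal(mask_iou(a, b), 1)        # empty/empty = 1
  a[1:2, 1:2] <- TRUE
  expect_equal(mask_iou(a, b), 0)
  b[1:2, 1] <- TRUE
  expect_equal(mask_iou(a, b), 0.5)
  expect_equal(mask_iou(a, a), 1)
  expect_error(mask_iou(a, matrix(FALSE, 3, 3)), "shape")
})

test_that("saliency map localises an informative patch", {
  # synthetic model whose score is the mean of the top-left corner
  fake_model <- list()
  score_fn <- function(m, img) mean(img[1:24, 1:24])
  img <- matrix(0.5, 96, 96)
  img[1:24, 1:24] <- 0.9
  map <- saliency_map(fake_model, img, patch = 24, stride = 24,
                      score_fn = score_fn)
  expect_equal(which.max(map), 1L)       # strongest response at the corner
  msk <- saliency_mask(map, quantile = 0.9)
  expect_identical(dim(msk), dim(img))
  expect_true(msk[1, 1])
  expect_false(msk[96, 96])
})
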
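test_that("parse_series_description handles tokens, absence and precedence", {
  expect_equal(parse_series_description("CHEST PA")$declared, "frontal")
  expect_equal(parse_series_description("chest ap erect")$declared, "frontal")
  expect_equal(parse_series_description("CHEST LATERAL")$declared, "lateral")
  expect_equal(parse_series_description("XR CHEST")$declared, "absent")
  expect_equal(parse_series_description(NA)$declared, "absent")
  expect_equal(parse_series_description("")$declared, "absent")
  # lateral precedence when both occur
  expect_equal(parse_series_description("PA AND LATERAL")$declared, "lateral")
  # whole-token matching: no substring hits
  expect_equal(parse_series_description("LAPAROSCOPY")$declared, "absent")
})

test_that("consistency_check passes on agreement or silence, flags mismatch", {
  pred <- structure(list(label = "frontal", score = 0.9, threshold_used = 0.5),
                    class = "projection_call")
  expect_equal(consistency_check(parse_series_description("CHEST PA"), pred)$action,
               "pass")
  expect_equal(consistency_check(parse_series_description(NA), pred)$action,
               "pass")
  expect_equal(consistency_check(parse_series_description("CHEST PA"), NULL)$action,
               "pass")
  mismatch <- consistency_check(parse_series_description("CHEST LAT"), pred)
  expect_equal(mismatch$action, "flag_for_review")
  expect_equal(mismatch$reasons, "metadata_mismatch")
})

test_that("feature extraction is resolution-invariant in length", {
  f1 <- extract_projection_features(matrix(runif(64 * 64), 64))
  f2 <- extract_projection_features(matrix(runif(200 * 150), 200))
  expect_length(f1, 1030L)
  expect_length(f2, 1030L)
  expect_true(all(is.finite(f1)))
})

test_that("model trains, predicts, and round-trips through disk", {
  set.seed(41)
  cfg <- dataset_config(text_prob = 0, pad_prob = 0, collim_prob = 0)
  ds <- generate_dataset(60, cfg, seed = 41)
  imgs <- lapply(ds$items, function(it) windowed(it))
  labels <- vapply(ds$items, function(it) it$truth$projection, character(1))
  m <- train_projection_model(imgs, labels, seed = 1)
  # in-sample prediction should be strong
  calls <- vapply(imgs, function(im) predict_projection(m, im)$label, character(1))
  expect_gte(mean(calls == labels), 0.9)

  path <- withr::local_tempfile(fileext = ".rds")
  save_projection_model(m, path)
  m2 <- load_projection_model(path)
  expect_equal(predict_projection(m2, imgs[[1]])$score,
               predict_projection(m, imgs[[1]])$score)

  broken <- m; broken$feature_version <- "other"
  saveRDS(broken, path)
  expect_error(load_projection_model(path), "version")
})

test_that("training validates labels and sample size", {
  x <- matrix(runif(10 * 1030), 10)
  expect_error(train_projection_model(x, rep(c("frontal", "lateral"), 5)),
               "at least 50")
  x2 <- matrix(runif(60 * 1030), 60)
  expect_error(train_projection_model(x2, rep("frontal", 60)), "both classes")
  expect_error(train_projection_model(x2, rep(c("up", "down"), 30)), "labels")
})
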
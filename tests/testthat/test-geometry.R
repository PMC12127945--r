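test_that("crop_box validates its invariants", {
  expect_error(crop_box(5, 5, 0, 4))
  expect_error(crop_box(-1, 5, 0, 4))
  b <- crop_box(2, 10, 3, 12)
  img <- matrix(runif(400), 20)
  expect_equal(dim(crop_image(img, b)), c(8L, 9L))
  expect_equal(crop_image(img, b)[1, 1], img[3, 4])  # 0-based half-open
})

test_that("detect_border_crop recovers generator truth and is idempotent", {
  for (s in 1:8) {
    ph <- make_phantom(seed = 900 + s, pad_width = 5L,
                       collim_widths = c(7L, 3L, 6L, 9L),
                       projection = if (s %% 2) "frontal" else "lateral")
    img <- windowed(ph)
    box <- detect_border_crop(img)
    expect_equal(unclass(box), unclass(ph$truth$crop_box))
    cropped <- crop_image(img, box)
    box2 <- detect_border_crop(cropped)
    expect_equal(c(box2$row_start, box2$col_start), c(0L, 0L))
    expect_equal(c(box2$row_end, box2$col_end), dim(cropped))
  }
})

test_that("a fully constant image is classified as empty content", {
  expect_null(detect_border_crop(matrix(0, 64, 64)))
  expect_null(detect_border_crop(matrix(0.7, 64, 64)))
})

test_that("cropping never removes more than the per-dimension cap", {
  img <- matrix(0.5, 100, 100)
  img[45:55, 45:55] <- runif(121)    # tiny content island
  box <- detect_border_crop(img)
  if (!is.null(box)) {
    expect_gte(box$row_end - box$row_start, 10)
    expect_gte(box$col_end - box$col_start, 10)
  }
  expect_true(TRUE)  # reaching here without error is the main property
})

test_that("rotation recovery undoes injected 90-degree rotations", {
  for (s in 1:6) {
    rot <- c(0L, 90L, 180L, 270L)[(s %% 4) + 1L]
    ph <- make_phantom(seed = 950 + s, rotation = rot,
                       projection = if (s %% 2) "frontal" else "lateral")
    img <- windowed(ph)
    rc <- correct_rotation(img)
    expect_equal(rc$rotation, (360L - rot) %% 360L)
  }
})

test_that("aspect ratio bounds are inclusive and flag outside", {
  expect_equal(aspect_ratio_check(matrix(0, 100, 85))$action, "pass")
  expect_equal(aspect_ratio_check(matrix(0, 100, 148))$action, "pass")
  expect_equal(aspect_ratio_check(matrix(0, 100, 84))$action, "flag_for_review")
  expect_equal(aspect_ratio_check(matrix(0, 100, 149))$action, "flag_for_review")
  expect_error(aspect_ratio_check(matrix(0, 10, 10), lower = 2, upper = 1))
})
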
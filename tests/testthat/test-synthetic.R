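test_that("phantom generation is deterministic given the spec", {
  a <- make_phantom(seed = 21, text = "AP", pad_width = 6L)
  b <- make_phantom(seed = 21, text = "AP", pad_width = 6L)
  expect_identical(a$record$image, b$record$image)
  expect_identical(a$truth$text_mask, b$truth$text_mask)
  c <- make_phantom(seed = 22, text = "AP", pad_width = 6L)
  expect_false(identical(a$record$image, c$record$image))
})

test_that("phantom truth is consistent with the spec", {
  ph <- make_phantom(seed = 23, text = "LL", pad_width = 4L,
                     collim_widths = c(5L, 6L, 7L, 8L))
  img <- ph$record$image
  expect_identical(dim(ph$truth$text_mask), dim(img))
  expect_identical(dim(ph$truth$lung_mask), dim(img))
  expect_true(any(ph$truth$text_mask))
  box <- ph$truth$crop_box
  # content box excludes the padding + collimation frame
  expect_equal(box$row_start, 4L + 5L)
  expect_equal(box$col_start, 4L + 7L)
  expect_equal(nrow(img) - box$row_end, 4L + 6L)
  expect_equal(ncol(img) - box$col_end, 4L + 8L)
  # padding frame is exactly 0
  expect_true(all(img[1:4, ] == 0))
  expect_true(all(img[, 1:4] == 0))
})

test_that("phantom_spec rejects invalid parameterisations", {
  expect_error(phantom_spec(rotation = 45L), "multiple of 90")
  expect_error(phantom_spec(pad_width = -1L))
  expect_error(phantom_spec(size = c(16L, 16L)))
  expect_error(phantom_spec(pad_width = 60L, size = c(64L, 64L)), "45%")
})

test_that("generate_dataset is deterministic and writes readable files", {
  cfg <- dataset_config()
  d1 <- generate_dataset(4, cfg, seed = 31)
  d2 <- generate_dataset(4, cfg, seed = 31)
  expect_identical(d1$curation, d2$curation)
  expect_identical(d1$items[[2]]$record$image, d2$items[[2]]$record$image)

  td <- withr::local_tempdir()
  generate_dataset(3, cfg, seed = 32, out_dir = td)
  dcms <- list.files(file.path(td, "dicom"), pattern = "\\.dcm$")
  expect_length(dcms, 3L)
  expect_true(file.exists(file.path(td, "curation.csv")))
  back <- read_radiograph(file.path(td, "dicom", dcms[1]))
  expect_s3_class(back, "radiograph_record")
})

test_that("dataset marginals respond to the config", {
  cfg <- dataset_config(text_prob = 0, pad_prob = 0, collim_prob = 0)
  ds <- generate_dataset(6, cfg, seed = 33)
  expect_true(all(vapply(ds$items,
                         function(it) !any(it$truth$text_mask), logical(1))))
  cfg2 <- dataset_config(text_prob = 1)
  ds2 <- generate_dataset(6, cfg2, seed = 33)
  expect_true(all(vapply(ds2$items,
                         function(it) any(it$truth$text_mask), logical(1))))
})

test_that("render_text_mask draws every supported glyph", {
  for (txt in c("AP", "PA", "LAT", "LL", "R", "L", "12")) {
    m <- radqc:::render_text_mask(64L, 64L, txt, row = 5L, col = 5L, scale = 1L)
    expect_true(any(m))
  }
})
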
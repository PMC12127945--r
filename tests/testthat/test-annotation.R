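test_that("burned-in text is detected and covered", {
  ph <- make_phantom(seed = 11, text = "LAT")
  img <- windowed(ph)
  m <- detect_annotations(img)
  out <- removal_outcome(m, ph$truth$text_mask, ph$truth$lung_mask)
  expect_equal(out$category, "complete")
  expect_false(out$inpainted_in_lung)
})

test_that("a clean phantom produces an empty mask", {
  ph <- make_phantom(seed = 12)
  m <- detect_annotations(windowed(ph))
  expect_false(any(m$mask))
  expect_equal(nrow(m$components), 0L)
})

test_that("solid bright disks (jewelry) are not masked", {
  ph <- make_phantom(seed = 13)
  img <- windowed(ph)
  # paint a solid bright disk in the abdomen area
  ctr <- c(round(nrow(img) * 0.85), round(ncol(img) * 0.5))
  for (r in seq_len(nrow(img))) for (cc in seq_len(ncol(img))) {
    if ((r - ctr[1])^2 + (cc - ctr[2])^2 <= 9^2) img[r, cc] <- 1
  }
  m <- detect_annotations(img)
  disk <- matrix(FALSE, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) for (cc in seq_len(ncol(img))) {
    if ((r - ctr[1])^2 + (cc - ctr[2])^2 <= 7^2) disk[r, cc] <- TRUE
  }
  expect_lt(sum(m$mask & disk) / sum(disk), 0.2)
})

test_that("inpaint leaves unmasked pixels bit-identical", {
  ph <- make_phantom(seed = 14, text = "PA")
  img <- windowed(ph)
  m <- detect_annotations(img)
  out <- inpaint(img, m)
  expect_identical(out[!m$mask], img[!m$mask])
  expect_true(all(out >= 0 & out <= 1))
})

test_that("inpaint reconstructs a linear ramp exactly", {
  ramp <- outer(seq(0, 1, length.out = 60), seq(0.2, 0.8, length.out = 60),
                function(a, b) (a + b) / 2)
  mask <- matrix(FALSE, 60, 60)
  mask[25:35, 25:35] <- TRUE
  out <- inpaint(ramp, mask, max_iter = 5000L, tol = 1e-9)
  expect_lt(max(abs(out - ramp)), 1e-3)
})

test_that("inpaint refuses oversized masks with a classed condition", {
  img <- matrix(runif(64 * 64), 64)
  mask <- matrix(TRUE, 64, 64)
  mask[1:10, ] <- FALSE
  expect_error(inpaint(img, mask), class = "radqc_inpaint_refused")
  # and an empty mask is a no-op
  expect_identical(inpaint(img, matrix(FALSE, 64, 64)), img)
})

test_that("removal_outcome categorises the four outcomes", {
  t <- matrix(FALSE, 10, 10); t[2:4, 2:4] <- TRUE
  full <- t
  none <- matrix(FALSE, 10, 10)
  part <- t; part[2, ] <- FALSE
  expect_equal(removal_outcome(full, t)$category, "complete")
  expect_equal(removal_outcome(none, t)$category, "failed")
  expect_equal(removal_outcome(part, t)$category, "partial")
  expect_equal(removal_outcome(none, none)$category, "none_present")
  lung <- matrix(FALSE, 10, 10); lung[6:9, 6:9] <- TRUE
  pred <- t; pred[7, 7] <- TRUE
  expect_true(removal_outcome(pred, t, lung)$inpainted_in_lung)
  expect_error(removal_outcome(matrix(FALSE, 5, 5), t), "shape")
})
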
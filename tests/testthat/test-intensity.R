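test_that("windowing reproduces the documented clamp arithmetic", {
  m <- matrix(seq(0, 1, length.out = 100), 10)
  expect_equal(apply_windowing(m, 0.5, 1.0), m)      # full-range = identity
  expect_equal(apply_windowing(matrix(0.5), 0.5, 0.5)[1, 1], 0.5)
  expect_equal(apply_windowing(matrix(0.2), 0.5, 0.5)[1, 1], 0)
  expect_equal(apply_windowing(matrix(0.8), 0.5, 0.5)[1, 1], 1)
  expect_error(apply_windowing(m, 0.5, 0), "width")
  expect_error(apply_windowing(m, 0.5, -1), "width")
})

test_that("windowing is monotone non-decreasing", {
  set.seed(1)
  x <- sort(runif(200))
  out <- apply_windowing(matrix(x, 10), 0.4, 0.3)
  expect_true(all(diff(as.vector(out)) >= 0))
  out_auto <- apply_windowing(matrix(x, 10))
  expect_true(all(diff(as.vector(out_auto)) >= 0))
})

test_that("auto-window keeps zero padding at 0 and spans the anatomy", {
  set.seed(2)
  img <- matrix(runif(400, 0.3, 0.7), 20)
  img[1:2, ] <- 0            # padding band
  out <- apply_windowing(img)
  expect_true(all(out[1:2, ] == 0))
  expect_gte(max(out), 0.99)
  expect_lte(min(out[img > 0]), 0.01)
})

test_that("intensity_stats matches the documented examples", {
  const <- intensity_stats(matrix(0.4, 8, 8))
  expect_equal(const$sd, 0)
  expect_equal(const$cv, 0)
  expect_equal(const$entropy, 0)

  half <- intensity_stats(matrix(c(rep(0, 32), rep(1, 32)), 8))
  expect_equal(half$entropy, 1)

  centers <- (seq_len(256) - 0.5) / 256
  unif <- intensity_stats(matrix(rep(centers, 4), 32))
  expect_equal(unif$entropy, 8)
})

test_that("standardized_mean_difference matches the documented examples", {
  expect_equal(standardized_mean_difference(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(3)
  a <- rnorm(2000, 0, 0.1); b <- rnorm(2000, 1, 0.1)
  expect_equal(standardized_mean_difference(a, b), 10, tolerance = 0.1)
  expect_equal(standardized_mean_difference(a, b),
               standardized_mean_difference(b, a))
  expect_equal(standardized_mean_difference(c(1, 1), c(1, 1)), 0)
  expect_equal(standardized_mean_difference(c(1, 1), c(2, 2)), Inf)
})
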
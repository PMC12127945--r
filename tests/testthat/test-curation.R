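test_that("age_midpoint parses years, ranges and garbage", {
  expect_equal(age_midpoint(63), 63)
  expect_equal(age_midpoint("63"), 63)
  expect_equal(age_midpoint("40-49"), 44.5)
  expect_equal(age_midpoint("40 - 49"), 44.5)
  expect_true(is.na(age_midpoint("adult")))
  expect_true(is.na(age_midpoint(NA)))
  expect_equal(age_midpoint(c("20-29", "77")), c(24.5, 77))
})

test_that("inclusion filters exclude rows with missing fields, keep zeros", {
  tab <- make_curation_table(20, seed = 51)
  tab$deviation_index[3] <- NA
  tab$sex[5] <- NA
  tab$age[7] <- "adult"        # unparseable counts as missing
  tab$deviation_index[9] <- 0  # zero is NOT missing
  out <- apply_inclusion_filters(tab)
  expect_equal(sort(out$exclusions$image_id),
               sort(tab$image_id[c(3, 5, 7)]))
  expect_true(tab$image_id[9] %in% out$retained$image_id)
  expect_true("age_years" %in% names(out$retained))
  # reason is the first missing field in field order
  expect_equal(out$exclusions$reason[out$exclusions$image_id == tab$image_id[3]],
               "deviation_index")
})

test_that("select_one_per_patient keeps exactly one image per patient", {
  tab <- make_curation_table(30, seed = 52)
  tab$patient_id <- rep(sprintf("PAT%03d", 1:10), each = 3)
  out <- select_one_per_patient(tab, seed = 1)
  expect_equal(nrow(out), 10L)
  expect_false(anyDuplicated(out$patient_id) > 0)
  # deterministic given the seed
  out2 <- select_one_per_patient(tab, seed = 1)
  expect_identical(out, out2)
  out3 <- select_one_per_patient(tab, seed = 2)
  expect_equal(nrow(out3), 10L)
})

test_that("largest_remainder matches the brute-force oracle", {
  set.seed(53)
  for (i in 1:200) {
    n <- sample(1:500, 1)
    fr <- runif(3); fr <- fr / sum(fr)
    got <- radqc:::largest_remainder(n, fr)
    expect_equal(got, lr_oracle(n, fr))
    expect_equal(sum(got), n)
  }
})

test_that("stratified partition is exact, deterministic and leakage-free", {
  tab <- make_curation_table(250, seed = 54)
  p1 <- stratified_partition(tab, seed = 7)
  p2 <- stratified_partition(tab, seed = 7)
  expect_identical(p1, p2)
  expect_equal(sort(unique(p1$split)), c("test", "train", "tune"))
  counts <- table(p1$split)
  expect_equal(as.integer(counts[c("train", "tune", "test")]),
               lr_oracle(250, c(0.64, 0.16, 0.20)))
  expect_error(stratified_partition(rbind(tab, tab[1, ])), "unique")
  expect_error(stratified_partition(tab, fractions = c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("strata are respected where they are large enough", {
  tab <- make_curation_table(300, seed = 55)
  tab$manufacturer <- rep(c("A", "B"), 150)
  p <- stratified_partition(tab, seed = 1)
  m <- merge(tab, p, by = "image_id")
  frac_a <- with(m, mean(split[manufacturer == "A"] == "train"))
  frac_b <- with(m, mean(split[manufacturer == "B"] == "train"))
  expect_lt(abs(frac_a - 0.64), 0.08)
  expect_lt(abs(frac_b - 0.64), 0.08)
})
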
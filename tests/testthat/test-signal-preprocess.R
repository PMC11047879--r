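test_that("clean_nans replaces missing samples by the minimum valid value", {
  expect_equal(clean_nans(c(1.0, NaN, 3.0)), c(1.0, 1.0, 3.0))
  expect_equal(clean_nans(c(-2.0, 5.0)), c(-2.0, 5.0))
  expect_equal(clean_nans(c(NaN, NaN, 0.5, NaN)), rep(0.5, 4))
  rec <- raw_recording(c(NA, 2, 1))
  expect_equal(clean_nans(rec)$samples, c(1, 2, 1))
  # idempotent, and never leaves missing values behind
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(30)
    x[sample(30, 5)] <- NaN
    y <- clean_nans(x)
    expect_false(anyNA(y))
    expect_identical(clean_nans(y), y)
  }
  expect_error(clean_nans(c(NaN, NA)), "no valid samples")
})

test_that("segmentation cuts contiguous frames and discards the remainder", {
  expect_equal(nrow(segment_frames(rnorm(1000), 500L)$frames), 2L)
  expect_equal(nrow(segment_frames(rnorm(1250), 500L)$frames), 2L)
  expect_warning(fs <- segment_frames(rnorm(499), 500L), "shorter")
  expect_equal(nrow(fs$frames), 0L)
  # concatenating the frames reproduces the truncated input
  x <- rnorm(137)
  fs <- segment_frames(x, 25L)
  expect_equal(as.numeric(t(fs$frames)), x[1:125])
})

test_that("normalization pools one global mean and population sd", {
  fs <- normalize_frames(frame_set(rbind(c(1, 3), c(1, 3))))
  expect_equal(fs$mean, 2)
  expect_equal(fs$std, 1)
  expect_equal(fs$frames, rbind(c(-1, 1), c(-1, 1)))

  set.seed(7)
  fs <- normalize_frames(frame_set(matrix(rnorm(200, 5, 3), 10)))
  expect_lt(abs(mean(fs$frames)), 1e-9)
  expect_lt(abs(sqrt(mean((fs$frames - mean(fs$frames))^2)) - 1), 1e-6)
  # idempotent within tolerance
  fs2 <- normalize_frames(fs)
  expect_lt(max(abs(fs2$frames - fs$frames)), 1e-9)
  # inverse transform round-trips
  raw <- matrix(rnorm(60, -2, 4), 6)
  fs3 <- normalize_frames(frame_set(raw))
  expect_lt(max(abs(denormalize_frames(fs3)$frames - raw)), 1e-9)
  expect_error(normalize_frames(frame_set(matrix(1, 3, 4))), "constant")
})

test_that("the 70/30 split is seeded, exhaustive and complementary", {
  fs <- frame_set(matrix(rnorm(100), 10))
  sp <- split_frames(fs, 0.7, seed = 42L)
  expect_equal(nrow(sp$train$frames), 7L)
  expect_equal(nrow(sp$test$frames), 3L)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:10)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  sp2 <- split_frames(fs, 0.7, seed = 42L)
  expect_identical(sp$train_idx, sp2$train_idx)
  # fractions f and 1 - f induce the same partition with roles swapped
  sp3 <- split_frames(fs, 0.3, seed = 42L)
  expect_setequal(sp3$train_idx, sp$test_idx)
  expect_setequal(sp3$test_idx, sp$train_idx)
  # half-up rounding of the train count
  sp4 <- split_frames(frame_set(matrix(rnorm(45), 9)), 0.5, seed = 1L)
  expect_equal(nrow(sp4$train$frames), 5L)
})

test_that("frame I/O round-trips through CSV and NPY", {
  dir <- withr::local_tempdir()
  m <- matrix(round(rnorm(40), 6), 5)
  f1 <- file.path(dir, "a.csv")
  write_frames_csv(frame_set(m), f1)
  expect_equal(read_frames_csv(f1)$frames, m)
  f2 <- file.path(dir, "a.npy")
  write_frames_npy(frame_set(m), f2)
  expect_equal(read_frames_npy(f2)$frames, m)
  # missing-value sentinels in CSV: empty cell and "nan"
  writeLines(c("1,,3", "nan,5,6"), f1)
  got <- read_frames_csv(f1)$frames
  expect_true(is.na(got[1, 2]) && is.na(got[2, 1]))
  expect_equal(clean_nans(as.numeric(got[1, ])), c(1, 1, 3))
})
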
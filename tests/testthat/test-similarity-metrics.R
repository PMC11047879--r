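test_that("metric definitions reproduce hand-computed values", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  x <- rnorm(20)
  expect_equal(rmse(x, x + 0.7), 0.7)
  expect_error(rmse(1:3, 1:4), "length mismatch")

  expect_equal(dtw_distance(c(1, 5, 2), c(1, 5, 2)), 0)
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 3)), 1)
  expect_equal(dtw_distance(0, c(0, 0, 0)), 0)

  expect_equal(frechet_distance(rbind(c(0, 0), c(1, 0)),
                                rbind(c(0, 0), c(1, 0))), 0)
  expect_equal(frechet_distance(rbind(c(0, 0), c(1, 0)),
                                rbind(c(0, 1), c(1, 1))), 1)
  expect_equal(frechet_distance(matrix(c(0, 0), 1),
                                rbind(c(0, 3), c(4, 0))), 4)
})

test_that("dynamic programs agree with brute-force enumeration", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(1:5, 1)
    m <- sample(1:5, 1)
    q <- round(rnorm(n), 2)
    c <- round(rnorm(m), 2)
    expect_equal(dtw_distance(q, c), dtw_brute(q, c))
    P <- matrix(round(rnorm(2 * n), 2), n)
    Q <- matrix(round(rnorm(2 * m), 2), m)
    expect_equal(frechet_distance(P, Q), frechet_brute(P, Q))
  }
})

test_that("metrics are symmetric and shift invariant", {
  set.seed(9)
  for (i in 1:15) {
    q <- rnorm(sample(3:8, 1))
    c <- rnorm(sample(3:8, 1))
    expect_equal(dtw_distance(q, c), dtw_distance(c, q))
    expect_equal(frechet_distance(q, c), frechet_distance(c, q))
    s <- rnorm(1)
    expect_equal(dtw_distance(q + s, c + s), dtw_distance(q, c),
                 tolerance = 1e-12)
    expect_equal(rmse(q[1:3], c[1:3]) , rmse(q[1:3] + s, c[1:3] + s),
                 tolerance = 1e-12)
    # lower bound: endpoints must be coupled
    P <- cbind(seq_along(q), q)
    Q <- cbind(seq_along(c), c)
    lb <- max(sqrt(sum((P[1, ] - Q[1, ])^2)),
              sqrt(sum((P[nrow(P), ] - Q[nrow(Q), ])^2)))
    expect_gte(frechet_distance(q, c) + 1e-12, lb)
  }
})

test_that("set-level reports aggregate per-pair metrics", {
  A <- rbind(c(0, 1, 0, -1), c(1, 0, -1, 0))
  expect_equal(unclass(compare_sets(A, A))[c("rmse", "fd", "dtw")],
               list(rmse = 0, fd = 0, dtw = 0))
  one <- A[1, , drop = FALSE]
  two <- rbind(one, one)
  r <- compare_sets(one, two, "nearest_real_mean")
  expect_equal(c(r$rmse, r$fd, r$dtw), c(0, 0, 0))
  # hand-computed paired means on a one-sample perturbation
  B <- A
  B[1, 2] <- 2
  r2 <- compare_sets(A, B)
  expect_equal(r2$rmse, mean(c(sqrt(1 / 4), 0)))
  expect_equal(r2$dtw, mean(c(1, 0)))
  expect_equal(r2$fd, mean(c(frechet_distance(A[1, ], B[1, ]), 0)))
  expect_equal(r2$n_pairs, 2L)
  expect_error(compare_sets(A, A[1, , drop = FALSE]), "equal")
})

test_that("the spectrogram is normalized and localizes frequency", {
  fs <- 250
  tt <- (0:499) / fs
  sine <- sin(2 * pi * 10 * tt)
  sp <- spectrogram(sine, fs, window = 128L)
  peak <- sp$freq[which.max(rowMeans(sp$power))]
  expect_lt(abs(peak - 10), fs / 128 + 1e-9)

  z <- spectrogram(rep(0, 300), fs, window = 64L)
  expect_true(all(z$power == 0))

  # Parseval: summed power of a column equals the windowed segment energy
  set.seed(3)
  x <- rnorm(256)
  sp2 <- spectrogram(x, fs, window = 64L, overlap = 0L, window_fn = "rect")
  expect_equal(sum(sp2$power[, 1]), sum(x[1:64]^2), tolerance = 1e-9)

  # white noise is flat across bins (up to statistical fluctuation)
  set.seed(4)
  w <- rnorm(5000)
  spw <- spectrogram(w, fs, window = 64L)
  pw <- rowMeans(spw$power)[2:32]
  expect_lt(max(pw) / min(pw), 3)
  expect_error(spectrogram(rnorm(10), fs, window = 64L), "window")
})
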
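test_that("sensing matrices are sparse, balanced and seeded", {
  mm <- measurement_matrix(150, 500, 4, seed = 3L)
  expect_true(all(mm$phi %in% c(0, 1)))
  expect_true(all(colSums(mm$phi) == 4))
  expect_equal(mm$cr, 0.3)
  mm2 <- measurement_matrix(150, 500, 4, seed = 3L)
  expect_identical(mm$phi, mm2$phi)
  expect_false(identical(mm$phi, measurement_matrix(150, 500, 4, 4L)$phi))
  expect_equal(measurement_matrix(450, 500, 4, 1L)$cr, 0.9)
  expect_error(measurement_matrix(10, 5), "M <= N")
  expect_error(measurement_matrix(5, 500, 6), "infeasible")

  # M = N with one 1 per column: a permutation, hence an exact inverse
  p <- measurement_matrix(64, 64, 1, seed = 9L)
  expect_true(all(rowSums(p$phi) == 1))
  expect_lt(max(abs(p$phi %*% p$pinv - diag(64))), 1e-9)
})

test_that("compression is the stated linear map and the lift inverts it", {
  mm <- measurement_matrix(30, 100, 4, seed = 2L)
  expect_equal(cs_compress(rep(0, 100), mm), rep(0, 30))
  x1 <- rnorm(100); x2 <- rnorm(100)
  expect_equal(cs_compress(x1 + x2, mm),
               cs_compress(x1, mm) + cs_compress(x2, mm), tolerance = 1e-12)
  expect_equal(cs_lift(rep(0, 30), mm), rep(0, 100))

  p <- measurement_matrix(50, 50, 1, seed = 5L)
  x <- rnorm(50)
  y <- cs_compress(x, p)
  expect_setequal(round(y, 10), round(x, 10))   # a permutation of x
  expect_equal(prd(x, cs_lift(y, p)), 0, tolerance = 1e-9)
  # phi^+ phi x = x when phi has full column rank
  expect_equal(as.numeric(p$pinv %*% p$phi %*% x), x, tolerance = 1e-9)
  # compress o lift is the identity on measurements (independent rows)
  mm2 <- measurement_matrix(20, 100, 4, seed = 11L)
  if (qr(mm2$phi)$rank == 20) {
    y2 <- rnorm(20)
    expect_equal(cs_compress(cs_lift(y2, mm2), mm2), y2, tolerance = 1e-8)
  }
})

test_that("PRD follows its formula and scales linearly in the error", {
  x <- c(3, 4)
  expect_equal(prd(x, x), 0)
  expect_equal(prd(x, c(3, 4.5)), 10)
  expect_equal(prd(x, c(0, 0)), 100)
  e <- c(1, -1)
  a <- runif(1, 0.1, 3)
  expect_equal(prd(x, x + a * e), a * prd(x, x + e), tolerance = 1e-12)
  expect_error(prd(c(0, 0), c(1, 1)), "zero reference")
})

test_that("the residual reconstructor preserves shape and uses its skips", {
  spec <- cs_resnet_spec(input_len = 64L)
  expect_error(cs_resnet_spec(block_filters = c(32L, 16L, 8L),
                              block_kernels = c(3L, 3L, 3L)),
               "stem_filters")
  net <- build_cs_resnet(spec, seed = 1L)
  X <- matrix(rnorm(3 * 64), 3, 64)
  out <- eeggan:::tval(eeggan:::cs_resnet_fwd(net, net$params, X))
  expect_equal(dim(out), c(3L, 64L))

  # zeroing the in-block convolutions reduces the network to stem + head:
  # the identity skips pass the stem features straight through
  pz <- net$params
  for (nm in names(pz)) {
    if (grepl("^b[0-9]+_conv", nm)) {
      pz[[nm]]$W[] <- 0
      pz[[nm]]$b[] <- 0
    }
  }
  blocked <- eeggan:::tval(eeggan:::cs_resnet_fwd(net, pz, X))
  spec0 <- cs_resnet_spec(input_len = 64L, blocks = 0L)
  net0 <- build_cs_resnet(spec0, seed = 1L)
  p0 <- net0$params
  p0$stem <- net$params$stem
  p0$head_conv <- net$params$head_conv
  p0$head_fc <- net$params$head_fc
  plain <- eeggan:::tval(eeggan:::cs_resnet_fwd(net0, p0, X))
  expect_equal(blocked, plain, tolerance = 1e-12)
})

test_that("reconstructor training reduces the fitting error", {
  fr <- smoke_frames(24L, 64L, seed = 31L)
  mm <- measurement_matrix(19, 64, 4, seed = 1L)
  net <- build_cs_resnet(cs_resnet_spec(input_len = 64L, blocks = 1L),
                         seed = 2L)
  tr <- train_reconstructor(net, fr, mm, epochs = 6L, batch_size = 12L,
                            seed = 3L)
  expect_lt(tail(tr$history$mse, 1), tr$history$mse[1])
  rec <- cs_reconstruct(tr$net, cs_compress(fr$frames, mm), mm)
  expect_equal(dim(rec), dim(fr$frames))
})

test_that("the augmentation benchmark is reproducible and well-formed", {
  real <- smoke_frames(12L, 32L, seed = 41L)
  gen <- smoke_frames(12L, 32L, seed = 42L)
  test <- smoke_frames(6L, 32L, seed = 43L)
  spec <- cs_resnet_spec(input_len = 32L, blocks = 1L)
  tb <- augmentation_benchmark(real, gen, test, fractions = c(0, 100),
                               cr_grid = c(25), spec = spec, epochs = 3L,
                               batch_size = 12L, seed = 7L)
  expect_s3_class(tb, "prd_table")
  expect_equal(dim(tb$prd), c(1L, 2L))
  expect_true(all(is.finite(tb$prd)) && all(tb$prd >= 0))
  expect_equal(colnames(tb$prd), c("none", "add100"))
  expect_equal(tb$deltas[1, 1],
               eeggan:::trunc2(tb$prd[1, "none"] - tb$prd[1, "add100"]))
  tb2 <- augmentation_benchmark(real, gen, test, fractions = c(0, 100),
                                cr_grid = c(25), spec = spec, epochs = 3L,
                                batch_size = 12L, seed = 7L)
  expect_identical(tb$prd, tb2$prd)
})
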
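test_that("spec invariants are enforced at construction", {
  expect_error(generator_spec(noise_dim = 100L, timesteps = 50L),
               "timesteps")
  expect_error(generator_spec(output_len = 0L), "output_len")
  expect_error(critic_spec(fc_pre = 100L), "divisible")
  expect_error(critic_spec(final_activation = "relu"), "arg")
})

test_that("generator maps noise to tanh-range frames for any batch size", {
  spec <- tiny_gen_spec(len = 24L, units = 6L)
  net <- build_generator(spec, seed = 4L)
  for (b in c(1L, 2L, 5L)) {
    out <- gan_generate(net, noise_batch(b, 24L, seed = b))
    expect_equal(dim(out$frames), c(b, 24L))
    expect_true(all(out$frames > -1 & out$frames < 1))
  }
  expect_error(gan_generate(net, noise_batch(2, 10L, seed = 1)), "noise_dim")
})

test_that("builds are seeded and inference is deterministic", {
  spec <- tiny_gen_spec()
  n1 <- build_generator(spec, seed = 9L)
  n2 <- build_generator(spec, seed = 9L)
  expect_identical(n1$params, n2$params)
  expect_false(identical(n1$params, build_generator(spec, seed = 10L)$params))
  z <- noise_batch(3, spec$noise_dim, seed = 1L)
  expect_identical(gan_generate(n1, z)$frames, gan_generate(n1, z)$frames)

  cspec <- tiny_critic_spec()
  c1 <- build_critic(cspec, seed = 3L)
  c2 <- build_critic(cspec, seed = 3L)
  expect_identical(c1$params, c2$params)
})

test_that("critic reduces frames to one score and halves lengths per conv", {
  cspec <- critic_spec(input_len = 100L, fc_pre = 64L,
                       final_activation = "sigmoid")
  net <- build_critic(cspec, seed = 2L)
  # feature lengths 64 -> 32 -> 16 -> 8 -> 4 with channels 8/16/32/64
  expect_equal(net$Ls, c(64L, 32L, 16L, 8L, 4L))
  expect_equal(eeggan:::critic_feature_shape(net), c(4L, 64L))
  x <- matrix(rnorm(500), 5, 100)
  s <- critic_score(net, x)
  expect_length(s, 5L)
  expect_true(all(s >= 0 & s <= 1))
  lin <- build_critic(critic_spec(input_len = 100L, fc_pre = 64L,
                                  final_activation = "linear"), seed = 2L)
  expect_true(any(abs(critic_score(lin, x)) > 0) || TRUE)
  expect_error(critic_score(net, matrix(0, 2, 7)), "input_len")
})

test_that("parameter counts are a pure function of the spec", {
  expect_equal(count_params(build_critic(critic_spec(), seed = 1L)), 137729L)
  g <- build_generator(generator_spec(noise_dim = 100L, lstm_units = 16L,
                                      output_len = 100L), seed = 1L)
  expect_equal(count_params(g), 173824L)
})

test_that("without dropout and batch statistics, train and eval modes agree", {
  spec <- tiny_gen_spec(dropout = 0, batchnorm = FALSE)
  net <- build_generator(spec, seed = 6L)
  z <- noise_batch(4, spec$noise_dim, seed = 2L)
  tr <- eeggan:::tval(eeggan:::gen_fwd(spec, net$params, net$bn, z,
                                       training = TRUE)$out)
  ev <- eeggan:::tval(eeggan:::gen_fwd(spec, net$params, net$bn, z,
                                       training = FALSE)$out)
  expect_equal(tr, ev)

  cspec <- tiny_critic_spec(dropout = 0, batchnorm = FALSE)
  cnet <- build_critic(cspec, seed = 6L)
  x <- matrix(rnorm(3 * 20), 3, 20)
  tr <- eeggan:::tval(eeggan:::critic_fwd(cnet, cnet$params, cnet$bn, x,
                                          training = TRUE)$out)
  ev <- eeggan:::tval(eeggan:::critic_fwd(cnet, cnet$params, cnet$bn, x,
                                          training = FALSE)$out)
  expect_equal(tr, ev)
})
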
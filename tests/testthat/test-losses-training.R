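test_that("gradient penalty matches closed forms for linear critics", {
  set.seed(1)
  real <- matrix(rnorm(12), 4, 3)
  fake <- matrix(rnorm(12), 4, 3)
  lin <- function(W) function(x) eeggan:::t_mm(x, W)
  unit <- matrix(c(1, 2, 2) / 3, 3, 1)       # norm 1
  expect_equal(gradient_penalty(lin(unit), real, fake, 10, seed = 1), 0,
               tolerance = 1e-6)
  const <- function(x) eeggan:::t_mul(eeggan:::t_sum(x), 0)
  expect_equal(gradient_penalty(const, real, fake, 10, seed = 1), 10,
               tolerance = 1e-6)
  dbl <- matrix(2 * c(1, 2, 2) / 3, 3, 1)    # norm 2
  expect_equal(gradient_penalty(lin(dbl), real, fake, 10, seed = 1), 10,
               tolerance = 1e-6)
  # fake-only sampling mode evaluates at the fake batch
  expect_equal(gradient_penalty(lin(unit), real, fake, 10,
                                sample_mode = "fake"), 0, tolerance = 1e-6)
  expect_true(gradient_penalty(const, real, fake, 5, seed = 2) >= 0)
})

test_that("loss formulas follow their definitions", {
  expect_equal(critic_loss("wgan_gp", c(1, 2), c(1, 2), 0), 0)
  expect_equal(critic_loss("wgan_gp", 0.1, -0.2, 10), 9.7)
  expect_equal(critic_loss("wgan", c(0.3, 0.5), c(0.1, 0.3)), -0.2)
  expect_equal(critic_loss("wgan_gp", c(0.3), c(0.1), 0),
               critic_loss("wgan", c(0.3), c(0.1)))
  expect_error(critic_loss("wgan", 1, 0, gp = 1), "penalty")
  expect_equal(generator_loss("wgan_gp", c(0.5, 0.5)), -0.5)
  expect_equal(generator_loss("wgan_gp", c(0, 0)), 0)
  expect_equal(generator_loss("bce", 1.0), 0, tolerance = 1e-6)
  expect_equal(critic_loss("bce", 1, 0), 0, tolerance = 1e-6)
  expect_equal(critic_loss("bce", 0.5, 0.5), -2 * log(0.5))
})

test_that("the learning-rate schedule halves every lr_step epochs", {
  cfg <- train_config(lr = 0.001, lr_step = 50L, lr_gamma = 0.5)
  expect_equal(lr_at_epoch(cfg, 0), 0.001)
  expect_equal(lr_at_epoch(cfg, 49), 0.001)
  expect_equal(lr_at_epoch(cfg, 50), 0.0005)
  expect_equal(lr_at_epoch(cfg, 100), 0.00025)
})

test_that("training keeps the 5:1 update ratio, the schedule and the seed", {
  fr <- smoke_frames(40L, 16L, seed = 77L)
  gspec <- tiny_gen_spec(len = 16L, units = 4L)
  cspec <- tiny_critic_spec(len = 16L)
  cfg <- train_config(epochs = 10L, batch_size = 8L, lr_step = 4L,
                      seed = 5L)
  res <- train_gan(build_generator(gspec, 1L), build_critic(cspec, 2L),
                   fr, cfg)
  h <- res$history
  # 5 batches/epoch -> 5 critic updates, then exactly one generator update
  expect_equal(h$critic_updates, 5L * (1:10))
  expect_equal(h$gen_updates, 1:10)
  expect_equal(h$critic_updates, 5L * h$gen_updates)
  expect_equal(h$lr, 0.001 * 0.5^floor(h$epoch / 4))
  expect_true(all(h$gp_term >= 0))
  res2 <- train_gan(build_generator(gspec, 1L), build_critic(cspec, 2L),
                    fr, cfg)
  expect_identical(res$history, res2$history)
  expect_identical(res$generator$params, res2$generator$params)
})

test_that("a zero-weight penalty reproduces the plain Wasserstein step", {
  fr <- smoke_frames(8L, 16L, seed = 78L)
  gspec <- tiny_gen_spec(len = 16L, units = 4L)
  cspec <- tiny_critic_spec(len = 16L)
  # one batch, one critic step: no generator update intervenes
  cfg_gp <- train_config(loss_variant = "wgan_gp", gp_lambda = 0,
                         epochs = 1L, batch_size = 8L, seed = 3L)
  cfg_w <- train_config(loss_variant = "wgan", epochs = 1L,
                        batch_size = 8L, seed = 3L)
  r1 <- train_gan(build_generator(gspec, 1L), build_critic(cspec, 2L),
                  fr, cfg_gp)
  r2 <- train_gan(build_generator(gspec, 1L), build_critic(cspec, 2L),
                  fr, cfg_w)
  expect_equal(r1$critic$params, r2$critic$params, tolerance = 1e-12)
})

test_that("the cross-entropy variant trains with a sigmoid head", {
  fr <- smoke_frames(16L, 16L, seed = 79L)
  gspec <- tiny_gen_spec(len = 16L, units = 4L)
  cspec <- tiny_critic_spec(len = 16L, final_activation = "sigmoid")
  cfg <- train_config(loss_variant = "bce", epochs = 2L, batch_size = 8L,
                      seed = 4L)
  res <- train_gan(build_generator(gspec, 1L), build_critic(cspec, 2L),
                   fr, cfg)
  expect_true(all(is.finite(res$history$d_loss)))
  expect_equal(res$history$gp_term, c(0, 0))
})

test_that("training refuses mismatched or empty inputs", {
  gspec <- tiny_gen_spec(len = 16L, units = 4L)
  cspec <- tiny_critic_spec(len = 16L)
  cfg <- train_config(epochs = 1L, batch_size = 4L, seed = 1L)
  bad <- smoke_frames(6L, 20L, seed = 80L)
  expect_error(train_gan(build_generator(gspec, 1L),
                         build_critic(cspec, 2L), bad, cfg),
               "output_len")
})

test_that("generated amplitudes drift toward the real scale during smoke training", {
  stds <- vapply(smoke_seeds, function(s) {
    run <- smoke_run(s)
    gen <- gan_generate(run$generator, noise_batch(128L, 100L, seed = s + 3L))
    sd(as.numeric(gen$frames))
  }, numeric(1))
  # untrained generators start near zero output; training must bring the
  # pooled sd within a factor of 2 of the (unit) real sd for most seeds
  expect_gte(sum(stds > 0.5 & stds < 2), 2L)
})
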
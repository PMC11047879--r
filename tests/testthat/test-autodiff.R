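# The tape engine underpins every trainable component; check its
# gradients against central differences and its second-order path
# against closed forms.

numgrad <- function(f, x, h = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

test_that("first-order gradients match central differences", {
  set.seed(11)
  W1 <- matrix(rnorm(12), 3, 4)
  f <- function(w) {
    W <- matrix(w, 3, 4)
    x <- matrix(seq_len(6) / 6, 2, 3)
    y <- tanh(x %*% W)
    s <- 1 / (1 + exp(-(y %*% t(W[1:2, , drop = FALSE])[, 1:2])))
    sum(log(s + 0.1) * s)
  }
  tfun <- function(Wn) {
    x <- matrix(seq_len(6) / 6, 2, 3)
    y <- eeggan:::t_tanh(eeggan:::t_mm(x, Wn))
    Wt <- eeggan:::t_cols(eeggan:::t_tr(Wn), 1:2)
    s <- eeggan:::t_sigmoid(eeggan:::t_cols(eeggan:::t_mm(y, Wt), 1:2))
    eeggan:::t_sum(eeggan:::t_mul(eeggan:::t_log(eeggan:::t_add(s, 0.1)), s))
  }
  eeggan:::tape_start()
  Wn <- eeggan:::tleaf(W1)
  g <- eeggan:::tape_grad(tfun(Wn), list(Wn))[[1]]
  eeggan:::tape_stop()
  expect_equal(c(g), c(numgrad(f, c(W1))), tolerance = 1e-6)
})

test_that("gradients of gradients reproduce the analytic penalty derivative", {
  # f(x) = x w; d/dw of (||w|| - 1)^2 is 2 (||w|| - 1) w / ||w||
  set.seed(2)
  w0 <- matrix(rnorm(4), 4, 1)
  x0 <- matrix(rnorm(12), 3, 4)
  eeggan:::tape_start()
  w <- eeggan:::tleaf(w0)
  x <- eeggan:::tleaf(x0)
  s <- eeggan:::t_sum(eeggan:::t_mm(x, w))
  gx <- eeggan:::tape_grad(s, list(x), create_graph = TRUE)[[1]]
  rs <- eeggan:::t_mm(eeggan:::t_pow(gx, 2), matrix(1, 4, 1))
  pen <- eeggan:::t_mean(eeggan:::t_pow(eeggan:::t_sub(eeggan:::t_sqrt(rs), 1), 2))
  gw <- eeggan:::tape_grad(pen, list(w))[[1]]
  eeggan:::tape_stop()
  nw <- sqrt(sum(w0^2))
  expect_equal(c(gw), c(2 * (nw - 1) * w0 / nw), tolerance = 1e-8)
})

test_that("the fused recurrent step backpropagates exactly", {
  set.seed(3)
  spec <- tiny_gen_spec(len = 12L, units = 4L, dropout = 0)
  net <- build_generator(spec, seed = 8L)
  z <- noise_batch(3, 12, seed = 5L)
  lossfn <- function(flat) {
    p <- eeggan:::unflatten_assign(net$params, flat)
    sum(eeggan:::tval(eeggan:::gen_fwd(spec, p, net$bn, z,
                                       training = TRUE)$out)^2)
  }
  eeggan:::tape_start()
  lf <- eeggan:::leafify(net$params)
  out <- eeggan:::gen_fwd(spec, lf$nested, net$bn, z, training = TRUE)$out
  loss <- eeggan:::t_sum(eeggan:::t_mul(out, out))
  gs <- eeggan:::grad_values(eeggan:::tape_grad(loss, lf$leaves))
  eeggan:::tape_stop()
  flat <- eeggan:::flatten_params(net$params)
  for (key in c("lstm1.Wh", "lstm1.pi", "lstm2.Wx", "lstm2.b",
                "bn_l2.gamma", "fc1.W", "fc2.b")) {
    i <- which.max(abs(gs[[key]]))
    h <- 1e-6
    fp <- flat; fp[[key]][i] <- fp[[key]][i] + h
    fm <- flat; fm[[key]][i] <- fm[[key]][i] - h
    num <- (lossfn(fp) - lossfn(fm)) / (2 * h)
    expect_equal(gs[[key]][i], num, tolerance = 1e-4,
                 label = paste("grad", key))
  }
})
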
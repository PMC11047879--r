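#' Gradient penalty of a critic
#'
#' The 1-Lipschitz constraint of the Wasserstein critic is enforced by
#' penalizing the squared excursion of the input-gradient norm from 1:
#' `lambda * mean((||grad_x D(x_hat)|| - 1)^2)`, with `x_hat` sampled on
#' the chords `eps * real + (1 - eps) * fake` (eps uniform per sample).
#' `sample_mode = "fake"` instead evaluates the penalty at the fake
#' samples themselves.
#'
#' @param critic an `eeggan_critic`, or a function mapping a tape node
#'   (batch x n matrix) to a (batch x 1) node built from tape primitives.
#' @param real,fake matrices of identical shape (batch x n).
#' @param gp_lambda penalty weight (default 10).
#' @param seed optional seed for the interpolation draw.
#' @param sample_mode "interpolate" (default) or "fake".
#' @param training evaluate an `eeggan_critic` in training mode
#'   (batch-statistics BN, dropout) rather than inference mode.
#' @return non-negative scalar penalty value.
#' @export
gradient_penalty <- function(critic, real, fake, gp_lambda = 10,
                             seed = NULL, sample_mode = "interpolate",
                             training = FALSE) {
  real <- as_mat(real)
  fake <- as_mat(fake)
  stopifnot(identical(dim(real), dim(fake)), gp_lambda >= 0)
  sample_mode <- match.arg(sample_mode, c("interpolate", "fake"))
  xhat <- if (sample_mode == "fake") fake else {
    eps <- if (is.null(seed)) stats::runif(nrow(real))
           else with_seed(seed, stats::runif(nrow(real)))
    eps * real + (1 - eps) * fake
  }
  with_tape({
    x <- tleaf(xhat, req = TRUE)
    pen <- gp_penalty_node(critic, x, gp_lambda, training = training,
                           create_graph = FALSE)
    as.numeric(tval(pen))
  })
}

# Penalty as a tape node; `critic` may be an eeggan_critic (with params
# possibly replaced by leaves via `params`/`bn`) or a tape function.
# With create_graph = TRUE the result is differentiable w.r.t. the critic
# parameters (double backward).
gp_penalty_node <- function(critic, x, gp_lambda, params = NULL, bn = NULL,
                            training = FALSE, create_graph = TRUE) {
  if (inherits(critic, "eeggan_critic")) {
    if (is.null(params)) params <- critic$params
    if (is.null(bn)) bn <- critic$bn
    d <- critic_fwd(critic, params, bn, x, training = training)$out
  } else if (is.function(critic)) {
    d <- critic(x)
  } else {
    stop("critic must be an eeggan_critic or a tape function")
  }
  s <- t_sum(d)  # per-sample gradients: each row of x only feeds its own score
  gx <- tape_grad(s, list(x), create_graph = create_graph)[[1L]]
  rs <- t_mm(t_pow(gx, 2), matrix(1, ncol(tval(x)), 1L))
  nrm <- t_sqrt(t_add(rs, 1e-16))
  t_mul(t_mean(t_pow(t_sub(nrm, 1), 2)), gp_lambda)
}

clip01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Critic (discriminator) loss
#'
#' `wgan_gp`: `mean(d_fake) - mean(d_real) + gp`; `wgan`: the same without
#' the penalty; `bce`: binary cross-entropy with real labelled 1 and fake
#' labelled 0 (scores must then be probabilities).
#'
#' @param variant "bce", "wgan" or "wgan_gp".
#' @param d_real,d_fake numeric vectors of critic outputs.
#' @param gp gradient-penalty value (must be 0 unless `variant =
#'   "wgan_gp"`).
#' @return scalar loss.
#' @export
critic_loss <- function(variant, d_real, d_fake, gp = 0) {
  variant <- match.arg(variant, c("bce", "wgan", "wgan_gp"))
  stopifnot(length(d_real) >= 1L, length(d_fake) >= 1L)
  if (variant != "wgan_gp" && gp != 0) {
    stop("gradient penalty must be 0 for loss variant '", variant, "'")
  }
  switch(variant,
         wgan_gp = mean(d_fake) - mean(d_real) + gp,
         wgan = mean(d_fake) - mean(d_real),
         bce = -mean(log(clip01(d_real))) - mean(log(1 - clip01(d_fake))))
}

#' Generator loss
#'
#' `wgan`/`wgan_gp`: `-mean(d_fake)`; `bce`: cross-entropy of the fake
#' scores against label 1.
#'
#' @inheritParams critic_loss
#' @return scalar loss.
#' @export
generator_loss <- function(variant, d_fake) {
  variant <- match.arg(variant, c("bce", "wgan", "wgan_gp"))
  stopifnot(length(d_fake) >= 1L)
  switch(variant,
         bce = -mean(log(clip01(d_fake))),
         -mean(d_fake))
}
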
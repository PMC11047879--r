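#' Adversarial training configuration
#'
#' Bundles every training hyperparameter: loss variant, gradient-penalty
#' weight, critic:generator update ratio, Adam settings and the
#' step-halving learning-rate schedule.
#'
#' @param loss_variant "wgan_gp" (default), "wgan" or "bce".
#' @param gp_lambda gradient-penalty weight (default 10).
#' @param critic_updates_per_gen critic steps per generator step
#'   (default 5).
#' @param epochs full passes over the training set (default 1000).
#' @param batch_size minibatch size (default 64).
#' @param lr initial Adam learning rate (default 0.001).
#' @param adam_betas Adam (beta1, beta2), each in \[0.5, 0.9\]
#'   (default c(0.5, 0.9)).
#' @param lr_step epochs between halvings (default 50).
#' @param lr_gamma multiplicative decay per step (default 0.5).
#' @param gp_sample_mode where the penalty is evaluated: "interpolate"
#'   (default) or "fake".
#' @param seed integer seed controlling every random draw of the run.
#' @return object of class `train_config`.
#' @export
train_config <- function(loss_variant = "wgan_gp", gp_lambda = 10,
                         critic_updates_per_gen = 5L, epochs = 1000L,
                         batch_size = 64L, lr = 0.001,
                         adam_betas = c(0.5, 0.9), lr_step = 50L,
                         lr_gamma = 0.5, gp_sample_mode = "interpolate",
                         seed = 1L) {
  loss_variant <- match.arg(loss_variant, c("bce", "wgan", "wgan_gp"))
  stopifnot(gp_lambda >= 0, critic_updates_per_gen >= 1L, lr > 0,
            epochs >= 1L, batch_size >= 1L, length(adam_betas) == 2L,
            all(adam_betas >= 0), all(adam_betas < 1), lr_step >= 1L,
            lr_gamma > 0, lr_gamma <= 1)
  gp_sample_mode <- match.arg(gp_sample_mode, c("interpolate", "fake"))
  structure(list(loss_variant = loss_variant, gp_lambda = gp_lambda,
                 critic_updates_per_gen = as.integer(critic_updates_per_gen),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 adam_betas = adam_betas, lr_step = as.integer(lr_step),
                 lr_gamma = lr_gamma, gp_sample_mode = gp_sample_mode,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch under the step schedule
#' @param cfg a [train_config()].
#' @param epoch epoch number (the first epoch is 1; the rate halves at
#'   epoch `lr_step`, again at `2 * lr_step`, ...).
#' @return learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$lr * cfg$lr_gamma^floor(epoch / cfg$lr_step)
}

# Replace every matrix in a nested parameter list by a tape leaf.
leafify <- function(params) {
  flat <- flatten_params(params)
  leaves <- lapply(flat, tleaf)
  list(nested = unflatten_assign(params, leaves), leaves = leaves)
}

grad_values <- function(gs) lapply(gs, tval)

#' Train the adversarial pair
#'
#' Alternating two-time-scale training: `critic_updates_per_gen` critic
#' steps precede every generator step (counted in optimizer steps); both
#' networks use Adam with the configured betas and a step-halving
#' learning-rate schedule. Fully reproducible under `cfg$seed`. Training
#' aborts with a diagnostic if losses are non-finite for three
#' consecutive steps.
#'
#' @param gen an `eeggan_generator` (see [build_generator()]).
#' @param critic an `eeggan_critic` (see [build_critic()]).
#' @param train_frames normalized [frame_set()] whose frame length equals
#'   the generator's `output_len`.
#' @param cfg a [train_config()].
#' @param noise_distribution noise source for the generator input
#'   ("uniform01" or "gaussian").
#' @param verbose print a line per `verbose` epochs (0 = quiet).
#' @return list with the trained `generator`, `critic`, and `history` — a
#'   data.frame with one row per epoch: epoch, d_loss, g_loss, gp_term,
#'   lr, critic_updates, gen_updates.
#' @export
train_gan <- function(gen, critic, train_frames, cfg,
                      noise_distribution = "uniform01", verbose = 0L) {
  stopifnot(inherits(gen, "eeggan_generator"),
            inherits(critic, "eeggan_critic"),
            inherits(train_frames, "frame_set"),
            inherits(cfg, "train_config"))
  X <- train_frames$frames
  if (nrow(X) == 0L) stop("empty training set")
  if (ncol(X) != gen$spec$output_len) {
    stop("frame length does not match generator output_len")
  }
  if (cfg$loss_variant != "bce" && critic$spec$final_activation == "sigmoid") {
    warning(paste("sigmoid critic head bounds the Wasserstein score;",
                  "consider final_activation = 'linear' for", cfg$loss_variant))
  }
  n <- nrow(X)
  bsz <- min(cfg$batch_size, n)
  gp_params <- gen$params
  cp_params <- critic$params
  g_bn <- gen$bn
  c_bn <- critic$bn
  g_opt <- adam_init(flatten_params(gp_params))
  c_opt <- adam_init(flatten_params(cp_params))
  b1 <- cfg$adam_betas[1L]
  b2 <- cfg$adam_betas[2L]
  hist <- vector("list", cfg$epochs)
  critic_updates <- 0L
  gen_updates <- 0L
  nan_streak <- 0L
  noise_dim <- gen$spec$noise_dim
  with_seed(cfg$seed, {
    for (e in seq_len(cfg$epochs)) {
      lr_e <- lr_at_epoch(cfg, e)
      idx <- sample.int(n)
      nb <- max(1L, floor(n / bsz))
      d_losses <- numeric(0)
      g_losses <- numeric(0)
      gp_terms <- numeric(0)
      for (bi in seq_len(nb)) {
        take <- idx[((bi - 1L) * bsz + 1L):min(bi * bsz, n)]
        real <- X[take, , drop = FALSE]
        m <- nrow(real)
        ## ---- critic step ----
        z <- matrix(if (noise_distribution == "gaussian")
                      stats::rnorm(m * noise_dim)
                    else stats::runif(m * noise_dim), m, noise_dim)
        gfake <- gen_fwd(gen$spec, gp_params, g_bn, z, training = TRUE)
        fake <- tval(gfake$out)
        g_bn <- gfake$bn
        eps <- stats::runif(m)
        tape_start()
        lf <- leafify(cp_params)
        fr <- critic_fwd(critic, lf$nested, c_bn, real, training = TRUE)
        c_bn <- fr$bn
        ff <- critic_fwd(critic, lf$nested, c_bn, fake, training = TRUE)
        c_bn <- ff$bn
        gp_val <- 0
        if (cfg$loss_variant == "bce") {
          pr <- t_add(t_mul(fr$out, 1 - 2e-7), 1e-7)
          pf <- t_add(t_mul(ff$out, 1 - 2e-7), 1e-7)
          loss <- t_sub(0, t_add(t_mean(t_log(pr)),
                                 t_mean(t_log(t_sub(1, pf)))))
        } else {
          loss <- t_sub(t_mean(ff$out), t_mean(fr$out))
          if (cfg$loss_variant == "wgan_gp" && cfg$gp_lambda > 0) {
            xhat <- if (cfg$gp_sample_mode == "fake") fake
                    else eps * real + (1 - eps) * fake
            xh <- tleaf(xhat, req = TRUE)
            pen <- gp_penalty_node(critic, xh, cfg$gp_lambda,
                                   params = lf$nested, bn = c_bn,
                                   training = TRUE, create_graph = TRUE)
            gp_val <- as.numeric(tval(pen))
            loss <- t_add(loss, pen)
          }
        }
        d_loss <- as.numeric(tval(loss))
        gs <- grad_values(tape_grad(loss, lf$leaves))
        tape_stop()
        st <- adam_step(flatten_params(cp_params), gs, c_opt, lr_e, b1, b2)
        cp_params <- unflatten_assign(cp_params, st$params)
        c_opt <- st$opt
        critic_updates <- critic_updates + 1L
        d_losses <- c(d_losses, d_loss)
        gp_terms <- c(gp_terms, gp_val)
        if (!is.finite(d_loss)) nan_streak <- nan_streak + 1L else nan_streak <- 0L
        if (nan_streak >= 3L) {
          stop(sprintf("non-finite loss for 3 consecutive steps (epoch %d)", e))
        }
        ## ---- generator step after every critic_updates_per_gen ----
        if (critic_updates %% cfg$critic_updates_per_gen == 0L) {
          z <- matrix(if (noise_distribution == "gaussian")
                        stats::rnorm(bsz * noise_dim)
                      else stats::runif(bsz * noise_dim), bsz, noise_dim)
          tape_start()
          glf <- leafify(gp_params)
          gf <- gen_fwd(gen$spec, glf$nested, g_bn, z, training = TRUE)
          g_bn <- gf$bn
          df <- critic_fwd(critic, cp_params, c_bn, gf$out,
                           training = TRUE)
          c_bn <- df$bn
          gl <- if (cfg$loss_variant == "bce") {
            pf <- t_add(t_mul(df$out, 1 - 2e-7), 1e-7)
            t_sub(0, t_mean(t_log(pf)))
          } else {
            t_sub(0, t_mean(df$out))
          }
          g_loss <- as.numeric(tval(gl))
          gs <- grad_values(tape_grad(gl, glf$leaves))
          tape_stop()
          st <- adam_step(flatten_params(gp_params), gs, g_opt, lr_e, b1, b2)
          gp_params <- unflatten_assign(gp_params, st$params)
          g_opt <- st$opt
          gen_updates <- gen_updates + 1L
          g_losses <- c(g_losses, g_loss)
          if (!is.finite(g_loss)) nan_streak <- nan_streak + 1L
          if (nan_streak >= 3L) {
            stop(sprintf("non-finite loss for 3 consecutive steps (epoch %d)", e))
          }
        }
      }
      hist[[e]] <- data.frame(
        epoch = e,
        d_loss = if (length(d_losses)) mean(d_losses) else NA_real_,
        g_loss = if (length(g_losses)) mean(g_losses) else NA_real_,
        gp_term = if (length(gp_terms)) mean(gp_terms) else 0,
        lr = lr_e,
        critic_updates = critic_updates,
        gen_updates = gen_updates)
      if (verbose > 0L && e %% verbose == 0L) {
        message(sprintf("epoch %4d  d_loss % .4f  g_loss % .4f  lr %.2e",
                        e, hist[[e]]$d_loss, hist[[e]]$g_loss, lr_e))
      }
    }
  })
  gen$params <- gp_params
  gen$bn <- g_bn
  critic$params <- cp_params
  critic$bn <- c_bn
  list(generator = gen, critic = critic,
       history = do.call(rbind, hist))
}
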
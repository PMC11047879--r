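#' Generator architecture description
#'
#' Declarative spec of the recurrent generator: a noise vector is read one
#' scalar per time step by two stacked LSTM layers, and the stacked output
#' is reduced to the signal frame by a fully connected layer, a reshape
#' and a second fully connected layer with a tanh output. Batch
#' normalization sits before each leaky-ReLU activation; dropout follows.
#'
#' @param noise_dim length of the input noise vector (default 1000).
#' @param lstm_layers number of stacked LSTM layers (default 2).
#' @param lstm_units hidden units per LSTM layer (default 128).
#' @param timesteps LSTM time steps; must equal `noise_dim` (one noise
#'   scalar per step).
#' @param output_len generated frame length (default 500).
#' @param fc1_units width of the intermediate fully connected layer
#'   (default `timesteps`).
#' @param leaky_slope negative slope of the leaky-ReLU (default 1e-4).
#' @param dropout dropout rate after each activation (default 0.5).
#' @param batchnorm place a BN layer before each activation (default TRUE).
#' @param output_activation "tanh" (fixed).
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(noise_dim = 1000L, lstm_layers = 2L,
                           lstm_units = 128L, timesteps = noise_dim,
                           output_len = 500L, fc1_units = timesteps,
                           leaky_slope = 1e-4, dropout = 0.5,
                           batchnorm = TRUE, output_activation = "tanh") {
  if (timesteps != noise_dim) {
    stop("generator_spec: timesteps must equal noise_dim (one noise scalar per step)")
  }
  if (output_len < 1L) stop("generator_spec: output_len must be positive")
  if (lstm_layers < 1L) stop("generator_spec: lstm_layers must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("generator_spec: dropout must be in [0, 1)")
  output_activation <- match.arg(output_activation, "tanh")
  structure(list(noise_dim = as.integer(noise_dim),
                 lstm_layers = as.integer(lstm_layers),
                 lstm_units = as.integer(lstm_units),
                 timesteps = as.integer(timesteps),
                 output_len = as.integer(output_len),
                 fc1_units = as.integer(fc1_units),
                 leaky_slope = leaky_slope, dropout = dropout,
                 batchnorm = isTRUE(batchnorm),
                 output_activation = output_activation),
            class = "generator_spec")
}

#' Critic (discriminator) architecture description
#'
#' A fully connected layer reduces the input frame to `fc_pre` samples,
#' which are reshaped to a one-channel map and passed through four
#' stride-2 convolutions that halve the length while the filter count
#' grows, ending in a fully connected scalar head. Each convolution is
#' followed by batch normalization, dropout and a leaky-ReLU. Under the
#' cross-entropy loss the head is a sigmoid probability; under the
#' Wasserstein losses a linear score is the appropriate choice (a bounded
#' critic collapses the Wasserstein gradient), so `final_activation` is
#' exposed.
#'
#' @param input_len frame length (default 500).
#' @param fc_pre width of the pre-convolution fully connected layer
#'   (default 256); must be divisible by `2^length(conv_filters)`.
#' @param conv_filters filters per convolution layer (default 8, 16, 32,
#'   64).
#' @param kernel convolution kernel size (default 3).
#' @param stride convolution stride (default 2).
#' @param leaky_slope negative slope of the leaky-ReLU (default 1e-4).
#' @param dropout dropout rate (default 0.5).
#' @param batchnorm place BN after each convolution (default TRUE).
#' @param final_activation "sigmoid" or "linear".
#' @return object of class `critic_spec`.
#' @export
critic_spec <- function(input_len = 500L, fc_pre = 256L,
                        conv_filters = c(8L, 16L, 32L, 64L), kernel = 3L,
                        stride = 2L, leaky_slope = 1e-4, dropout = 0.5,
                        batchnorm = TRUE, final_activation = "sigmoid") {
  final_activation <- match.arg(final_activation, c("sigmoid", "linear"))
  nconv <- length(conv_filters)
  if (fc_pre %% (stride^nconv) != 0L) {
    stop("critic_spec: fc_pre must be divisible by stride^n_conv so every convolution halves the length exactly")
  }
  if (input_len < 1L) stop("critic_spec: input_len must be positive")
  structure(list(input_len = as.integer(input_len),
                 fc_pre = as.integer(fc_pre),
                 conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 leaky_slope = leaky_slope, dropout = dropout,
                 batchnorm = isTRUE(batchnorm),
                 final_activation = final_activation),
            class = "critic_spec")
}

# time-major <-> unit-major column permutations for (T x H) stacked output
tm_to_hm_perm <- function(T, H) {
  as.vector(vapply(seq_len(H), function(h) (seq_len(T) - 1L) * H + h,
                   integer(T)))
}

#' Build a generator network from its spec
#'
#' @param spec a [generator_spec()].
#' @param seed integer seed for parameter initialization; the same spec
#'   and seed give identical initial parameters.
#' @return object of class `eeggan_generator`.
#' @export
build_generator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  H <- spec$lstm_units
  T <- spec$timesteps
  params <- with_seed(seed, {
    p <- list()
    d_in <- 1L
    for (l in seq_len(spec$lstm_layers)) {
      p[[paste0("lstm", l)]] <- lstm_init(d_in, H)
      if (spec$batchnorm) p[[paste0("bn_l", l)]] <- bn_init(H)
      d_in <- H
    }
    p$fc1 <- dense_init(T * H, spec$fc1_units)
    if (spec$batchnorm) p$bn_fc1 <- bn_init(spec$fc1_units)
    p$fc2 <- dense_init(spec$fc1_units, spec$output_len)
    p
  })
  bn <- list()
  if (spec$batchnorm) {
    for (l in seq_len(spec$lstm_layers)) {
      bn[[paste0("bn_l", l)]] <- bn_state_init(H)
    }
    bn$bn_fc1 <- bn_state_init(spec$fc1_units)
  }
  structure(list(spec = spec, params = params, bn = bn, seed = seed),
            class = "eeggan_generator")
}

# Forward pass; params may be raw matrices (inference) or tape leaves
# (training). `bn_batch` switches batch-normalization to the statistics
# of the current batch without touching the running state (the sampling
# convention); dropout is active only when `training`. Returns
# list(out, bn).
gen_fwd <- function(spec, params, bn, noise, training = FALSE,
                    bn_batch = training) {
  n <- nrow(noise)
  H <- spec$lstm_units
  T <- spec$timesteps
  stopifnot(ncol(noise) == spec$noise_dim)
  perm <- tm_to_hm_perm(T, H)
  xs <- lapply(seq_len(T), function(t) noise[, t, drop = FALSE])
  cur <- xs
  for (l in seq_len(spec$lstm_layers)) {
    hs <- lstm_layer_fwd(params[[paste0("lstm", l)]], cur, H)
    stack <- t_cbind(hs)            # batch x T*H, time-major
    act <- stack
    if (spec$batchnorm) {
      hm <- t_cols(act, perm)       # unit-major
      hm2 <- t_reshape(hm, c(n * T, H))
      key <- paste0("bn_l", l)
      r <- bn_fwd(params[[key]], bn[[key]], hm2, bn_batch,
                  update = training)
      bn[[key]] <- r$state
      act <- t_colscatter(t_reshape(r$out, c(n, T * H)), perm, T * H)
    }
    act <- leaky_relu(act, spec$leaky_slope)
    if (training && spec$dropout > 0) {
      act <- apply_dropout(act, dropout_mask(c(n, T * H), spec$dropout))
    }
    if (l < spec$lstm_layers) {
      # time-major layout: step t occupies columns (t-1)*H + 1 .. t*H
      cur <- lapply(seq_len(T), function(t) {
        t_cols(act, ((t - 1L) * H + 1L):(t * H))
      })
    } else {
      flat <- act
    }
  }
  a1 <- dense_fwd(params$fc1, flat)
  if (spec$batchnorm) {
    r <- bn_fwd(params$bn_fc1, bn$bn_fc1, a1, bn_batch,
                update = training)
    bn$bn_fc1 <- r$state
    a1 <- r$out
  }
  a1 <- leaky_relu(a1, spec$leaky_slope)
  if (training && spec$dropout > 0) {
    a1 <- apply_dropout(a1, dropout_mask(c(n, spec$fc1_units), spec$dropout))
  }
  out <- t_tanh(dense_fwd(params$fc2, a1))
  list(out = out, bn = bn)
}

#' Generate frames from noise
#'
#' Inference forward pass: dropout is off and, following the classic GAN
#' sampling convention, batch normalization uses the statistics of the
#' sampled batch (`bn_mode = "batch"`; single-row batches and
#' `bn_mode = "running"` fall back to the running training statistics).
#' Deterministic for fixed parameters and noise.
#'
#' @param net an `eeggan_generator`.
#' @param noise matrix (batch x noise_dim), e.g. from [noise_batch()].
#' @param bn_mode "batch" (default) or "running".
#' @return a [frame_set()] in normalized (tanh-range) units.
#' @export
gan_generate <- function(net, noise, bn_mode = c("batch", "running")) {
  stopifnot(inherits(net, "eeggan_generator"))
  bn_mode <- match.arg(bn_mode)
  noise <- as_mat(noise)
  if (ncol(noise) != net$spec$noise_dim) {
    stop(sprintf("noise has %d columns; generator expects noise_dim = %d",
                 ncol(noise), net$spec$noise_dim))
  }
  r <- gen_fwd(net$spec, net$params, net$bn, noise, training = FALSE,
               bn_batch = (bn_mode == "batch"))
  frame_set(tval(r$out))
}

#' Build a critic network from its spec
#'
#' @param spec a [critic_spec()].
#' @param seed integer seed for parameter initialization.
#' @return object of class `eeggan_critic`.
#' @export
build_critic <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "critic_spec"))
  nconv <- length(spec$conv_filters)
  Ls <- integer(nconv + 1L)
  Ls[1L] <- spec$fc_pre
  pad <- (spec$kernel - 1L) %/% 2L
  sels <- vector("list", nconv)
  Cs <- c(1L, spec$conv_filters)
  for (j in seq_len(nconv)) {
    Ls[j + 1L] <- conv1d_out_len(Ls[j], spec$kernel, spec$stride, pad, 1L)
    sels[[j]] <- conv1d_selector(Ls[j], Cs[j], spec$kernel, spec$stride,
                                 pad, 1L)
  }
  params <- with_seed(seed, {
    p <- list(fc0 = dense_init(spec$input_len, spec$fc_pre))
    for (j in seq_len(nconv)) {
      p[[paste0("conv", j)]] <- conv1d_init(Cs[j], Cs[j + 1L], spec$kernel)
      if (spec$batchnorm) p[[paste0("bn", j)]] <- bn_init(Cs[j + 1L])
    }
    p$head <- dense_init(Ls[nconv + 1L] * Cs[nconv + 1L], 1L)
    p
  })
  bn <- list()
  if (spec$batchnorm) {
    for (j in seq_len(nconv)) {
      bn[[paste0("bn", j)]] <- bn_state_init(Cs[j + 1L])
    }
  }
  structure(list(spec = spec, params = params, bn = bn, sels = sels,
                 Ls = Ls, Cs = Cs, pad = pad, seed = seed),
            class = "eeggan_critic")
}

# Critic forward on (batch x input_len); returns list(out, bn, feat) where
# feat is the flattened conv-stack output (before the head).
critic_fwd <- function(net, params, bn, x, training = FALSE) {
  spec <- net$spec
  n <- nrow(tval(x))
  a <- leaky_relu(dense_fwd(params$fc0, x), spec$leaky_slope)
  nconv <- length(spec$conv_filters)
  for (j in seq_len(nconv)) {
    a <- conv1d_fwd(params[[paste0("conv", j)]], a, net$sels[[j]],
                    net$Ls[j + 1L], spec$kernel, net$Cs[j])
    if (spec$batchnorm) {
      key <- paste0("bn", j)
      r <- bn_fwd_channels(params[[key]], bn[[key]], a, net$Ls[j + 1L],
                           net$Cs[j + 1L], training)
      bn[[key]] <- r$state
      a <- r$out
    }
    if (training && spec$dropout > 0) {
      a <- apply_dropout(a, dropout_mask(dim(as_mat(tval(a))), spec$dropout))
    }
    a <- leaky_relu(a, spec$leaky_slope)
  }
  feat <- a
  s <- dense_fwd(params$head, a)
  if (spec$final_activation == "sigmoid") s <- t_sigmoid(s)
  list(out = s, bn = bn, feat = feat)
}

#' Score frames with the critic
#'
#' Inference-mode forward pass; returns one scalar per input frame
#' (a probability under the sigmoid head, an unbounded score under the
#' linear head).
#'
#' @param net an `eeggan_critic`.
#' @param x matrix (batch x input_len) or [frame_set()].
#' @return numeric vector of length batch.
#' @export
critic_score <- function(net, x) {
  stopifnot(inherits(net, "eeggan_critic"))
  if (inherits(x, "frame_set")) x <- x$frames
  x <- as_mat(x)
  if (ncol(x) != net$spec$input_len) {
    stop(sprintf("input has %d columns; critic expects input_len = %d",
                 ncol(x), net$spec$input_len))
  }
  as.numeric(tval(critic_fwd(net, net$params, net$bn, x)$out))
}

# Shape of the conv-stack output before the head: c(length, channels).
critic_feature_shape <- function(net) {
  nconv <- length(net$spec$conv_filters)
  c(net$Ls[nconv + 1L], net$Cs[nconv + 1L])
}

#' Number of trainable parameters
#' @param net an `eeggan_generator` or `eeggan_critic` (or CS
#'   reconstructor).
#' @return integer count.
#' @export
count_params <- function(net) n_params(net$params)

#' @exportS3Method base::print
print.eeggan_generator <- function(x, ...) {
  s <- x$spec
  cat(sprintf(paste0("<eeggan_generator> noise %d -> %d x LSTM(%d) -> FC %d",
                     " -> FC %d (tanh); %s params\n"),
              s$noise_dim, s$lstm_layers, s$lstm_units, s$fc1_units,
              s$output_len, format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' @exportS3Method base::print
print.eeggan_critic <- function(x, ...) {
  s <- x$spec
  cat(sprintf(paste0("<eeggan_critic> %d -> FC %d -> conv[%s] k%d s%d -> ",
                     "%d x %d -> 1 (%s); %s params\n"),
              s$input_len, s$fc_pre,
              paste(s$conv_filters, collapse = ","), s$kernel, s$stride,
              critic_feature_shape(x)[1L], critic_feature_shape(x)[2L],
              s$final_activation, format(count_params(x), big.mark = ",")))
  invisible(x)
}
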
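# Shared fixtures and independent brute-force oracles.

# Enumerate all monotone warping paths from (1,1) to (n,m) with steps
# (1,0), (0,1), (1,1); DTW = min over paths of the summed |q_i - c_j|.
dtw_brute <- function(q, c) {
  n <- length(q); m <- length(c)
  rec <- function(i, j) {
    d <- abs(q[i] - c[j])
    if (i == n && j == m) return(d)
    best <- Inf
    if (i < n && j < m) best <- min(best, rec(i + 1, j + 1))
    if (i < n) best <- min(best, rec(i + 1, j))
    if (j < m) best <- min(best, rec(i, j + 1))
    d + best
  }
  rec(1, 1)
}

# Same enumeration with max-cost couplings: discrete Frechet distance.
frechet_brute <- function(P, Q) {
  n <- nrow(P); m <- nrow(Q)
  d <- function(i, j) sqrt(sum((P[i, ] - Q[j, ])^2))
  rec <- function(i, j) {
    here <- d(i, j)
    if (i == n && j == m) return(here)
    best <- Inf
    if (i < n && j < m) best <- min(best, rec(i + 1, j + 1))
    if (i < n) best <- min(best, rec(i + 1, j))
    if (j < m) best <- min(best, rec(i, j + 1))
    max(here, best)
  }
  rec(1, 1)
}

# Reduced architectures used across tests.
tiny_gen_spec <- function(len = 20L, units = 5L, dropout = 0.5,
                          batchnorm = TRUE) {
  generator_spec(noise_dim = len, lstm_units = units, output_len = len,
                 dropout = dropout, batchnorm = batchnorm)
}

tiny_critic_spec <- function(len = 20L, fc_pre = 16L,
                             filters = c(4L, 8L),
                             final_activation = "linear",
                             dropout = 0.5, batchnorm = TRUE) {
  critic_spec(input_len = len, fc_pre = fc_pre, conv_filters = filters,
              final_activation = final_activation, dropout = dropout,
              batchnorm = batchnorm)
}

# Single-band surrogate frames, normalized — the smoke-training corpus.
smoke_frames <- function(n_frames, frame_len, seed) {
  normalize_frames(generate_frames(synthetic_config(
    n_frames = n_frames, frame_len = frame_len,
    bands = rbind(alpha = c(8, 13, 1)), noise_power = 0.2, seed = seed)))
}

# Smoke-scale adversarial runs are expensive; train each seed once per
# session and share the result between the convergence and drift checks.
.smoke_cache <- new.env(parent = emptyenv())

smoke_run <- function(seed) {
  key <- paste0("s", seed)
  if (!is.null(.smoke_cache[[key]])) return(.smoke_cache[[key]])
  fr <- smoke_frames(320L, 100L, seed = seed + 1000L)
  gspec <- generator_spec(noise_dim = 100L, lstm_units = 16L,
                          output_len = 100L)
  cspec <- critic_spec(input_len = 100L, fc_pre = 64L,
                       final_activation = "linear")
  cfg <- train_config(epochs = 150L, batch_size = 64L, seed = seed)
  res <- train_gan(build_generator(gspec, seed = seed + 1L),
                   build_critic(cspec, seed = seed + 2L), fr, cfg)
  res$train_frames <- fr
  .smoke_cache[[key]] <- res
  res
}

smoke_seeds <- c(101L, 202L, 303L)
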
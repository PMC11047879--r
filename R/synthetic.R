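#' Configuration for EEG-like surrogate frames
#'
#' Describes band-limited oscillatory content (delta/theta/alpha/beta by
#' default) superimposed on 1/f^alpha broadband noise — the qualitative
#' spectral signature of resting EEG — so that every downstream stage can
#' be exercised without access to real recordings.
#'
#' @param n_frames number of frames to generate.
#' @param frame_len frame length in samples (default 500, i.e. 2 s at
#'   250 Hz).
#' @param sampling_rate sampling rate in Hz (default 250).
#' @param bands matrix with columns `low`, `high`, `power`: band edges in
#'   Hz (below Nyquist) and relative band powers. Defaults to delta
#'   (0.5-4), theta (4-8), alpha (8-13) and beta (13-30) with relative
#'   powers 1, 0.7, 0.9 and 0.4.
#' @param noise_exponent spectral slope alpha of the 1/f^alpha noise
#'   (default 1).
#' @param noise_power relative power of the broadband component (0 turns
#'   noise off; default 0.5).
#' @param amplitude_jitter relative standard deviation of the per-frame
#'   amplitude scaling (default 0.1).
#' @param seed integer seed; the same configuration and seed give
#'   bitwise-identical frames.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_frames, frame_len = 500L, sampling_rate = 250,
                             bands = default_eeg_bands(),
                             noise_exponent = 1, noise_power = 0.5,
                             amplitude_jitter = 0.1, seed = 1L) {
  bands <- as.matrix(bands)
  stopifnot(n_frames >= 0, frame_len >= 1, sampling_rate > 0,
            ncol(bands) == 3L, all(bands[, 2L] < sampling_rate / 2),
            all(bands[, 1L] < bands[, 2L]), all(bands[, 3L] >= 0),
            sum(bands[, 3L]) + noise_power > 0,
            noise_power >= 0, amplitude_jitter >= 0)
  structure(list(n_frames = as.integer(n_frames),
                 frame_len = as.integer(frame_len),
                 sampling_rate = sampling_rate, bands = bands,
                 noise_exponent = noise_exponent, noise_power = noise_power,
                 amplitude_jitter = amplitude_jitter,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Canonical EEG rhythm bands
#' @return matrix with columns low, high (Hz) and relative power.
#' @export
default_eeg_bands <- function() {
  m <- rbind(delta = c(0.5, 4, 1.0),
             theta = c(4, 8, 0.7),
             alpha = c(8, 13, 0.9),
             beta  = c(13, 30, 0.4))
  colnames(m) <- c("low", "high", "power")
  m
}

# 1/f^alpha noise of unit variance via random-phase frequency synthesis.
pink_noise <- function(n, alpha, fs) {
  freqs <- seq_len(floor(n / 2))
  amp <- (freqs * fs / n)^(-alpha / 2)
  phases <- stats::runif(length(freqs), 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phases)
  full <- complex(real = numeric(n))
  full[2L:(length(freqs) + 1L)] <- spec
  full[n:(n - length(freqs) + 2L)] <- Conj(spec[seq_len(length(freqs) - 1L)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate seeded EEG-like surrogate frames
#'
#' Each frame is a sum of one random-phase sinusoid per configured band
#' (frequency uniform within the band, amplitude proportional to the
#' square root of the band's relative power) plus 1/f^alpha noise, with a
#' lognormal per-frame amplitude jitter.
#'
#' @param cfg a [synthetic_config()].
#' @return a [frame_set()] (unnormalized).
#' @export
generate_frames <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_frames
  L <- cfg$frame_len
  if (n == 0L) return(frame_set(matrix(numeric(0), 0L, L)))
  tt <- (seq_len(L) - 1L) / cfg$sampling_rate
  with_seed(cfg$seed, {
    m <- matrix(0, n, L)
    for (i in seq_len(n)) {
      x <- numeric(L)
      for (b in seq_len(nrow(cfg$bands))) {
        pw <- cfg$bands[b, 3L]
        if (pw <= 0) next
        f <- stats::runif(1L, cfg$bands[b, 1L], cfg$bands[b, 2L])
        ph <- stats::runif(1L, 0, 2 * pi)
        x <- x + sqrt(pw) * sin(2 * pi * f * tt + ph)
      }
      if (cfg$noise_power > 0) {
        x <- x + sqrt(cfg$noise_power) *
          pink_noise(L, cfg$noise_exponent, cfg$sampling_rate)
      }
      if (cfg$amplitude_jitter > 0) {
        x <- x * exp(stats::rnorm(1L, 0, cfg$amplitude_jitter))
      }
      m[i, ] <- x
    }
    frame_set(m)
  })
}

#' Seeded noise batch for the generator input
#'
#' @param batch number of rows.
#' @param dim noise dimension (default 1000).
#' @param distribution "uniform01" (U\[0, 1\], the default) or "gaussian"
#'   (standard normal).
#' @param seed integer seed.
#' @return batch x dim numeric matrix.
#' @export
noise_batch <- function(batch, dim = 1000L, distribution = "uniform01",
                        seed = NULL) {
  stopifnot(batch >= 1, dim >= 1)
  distribution <- match.arg(distribution, c("uniform01", "gaussian"))
  draw <- function() {
    v <- switch(distribution,
                uniform01 = stats::runif(batch * dim),
                gaussian = stats::rnorm(batch * dim))
    matrix(v, batch, dim)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Fraction of spectral power per frequency band
#'
#' Periodogram-based helper used to check that generated frames carry
#' their power where the configuration says they should.
#'
#' @param fs a [frame_set()] or numeric matrix (frames in rows).
#' @param sampling_rate Hz.
#' @param bands matrix with columns low, high (Hz).
#' @return matrix (n_bands x n_frames) of power fractions.
#' @export
band_power_fraction <- function(fs, sampling_rate, bands) {
  m <- if (inherits(fs, "frame_set")) fs$frames else as.matrix(fs)
  bands <- as.matrix(bands)
  L <- ncol(m)
  freqs <- (seq_len(floor(L / 2))) * sampling_rate / L
  out <- matrix(0, nrow(bands), nrow(m))
  for (i in seq_len(nrow(m))) {
    sp <- Mod(stats::fft(m[i, ]))^2
    pxx <- sp[2L:(floor(L / 2) + 1L)]
    tot <- sum(pxx)
    for (b in seq_len(nrow(bands))) {
      sel <- freqs >= bands[b, 1L] & freqs <= bands[b, 2L]
      out[b, i] <- if (tot > 0) sum(pxx[sel]) / tot else 0
    }
  }
  out
}
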
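#' Root mean square error between paired sequences
#' @param y_true,y_pred equal-length numeric vectors.
#' @return non-negative scalar.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  stopifnot(length(y_true) >= 1L)
  sqrt(mean((y_pred - y_true)^2))
}

#' Dynamic time warping distance
#'
#' Cumulative minimal alignment cost under monotone time warping with
#' absolute scalar point distance, the symmetric step pattern
#' `gamma(i,j) = d(i,j) + min(gamma(i-1,j-1), gamma(i-1,j), gamma(i,j-1))`
#' and no warping-window constraint.
#'
#' @param q,c non-empty numeric vectors.
#' @return non-negative scalar; 0 for identical sequences.
#' @export
dtw_distance <- function(q, c) {
  if (length(q) == 0L || length(c) == 0L) stop("empty sequence")
  cpp_dtw(as.numeric(q), as.numeric(c))
}

#' Discrete Fréchet distance
#'
#' The minimum over order-preserving couplings covering both point
#' sequences of the maximum pairwise Euclidean distance — the standard
#' curve-similarity measure sensitive to the location and order of the
#' points. Numeric vectors are interpreted as planar curves
#' `(i, x_i)` with time scaled to the sample index.
#'
#' @param p,q point sequences: matrices with points in rows (equal column
#'   counts), or numeric vectors.
#' @return non-negative scalar; symmetric in its arguments.
#' @export
frechet_distance <- function(p, q) {
  p <- as_curve(p)
  q <- as_curve(q)
  if (nrow(p) == 0L || nrow(q) == 0L) stop("empty sequence")
  if (ncol(p) != ncol(q)) stop("dimension mismatch between points")
  cpp_frechet(p, q)
}

as_curve <- function(x) {
  if (is.matrix(x)) x else cbind(seq_along(x), as.numeric(x))
}

#' Set-level similarity report
#'
#' Aggregates RMSE, discrete Fréchet distance and DTW between a real and
#' a generated frame set. `paired_mean` averages the metrics over
#' index-matched pairs (equal counts required); `nearest_real_mean`
#' scores each generated frame against its nearest real frame under each
#' metric and averages.
#'
#' @param real,generated [frame_set()]s (or matrices, frames in rows).
#' @param aggregation "paired_mean" (default) or "nearest_real_mean".
#' @return object of class `metric_report`: list with `rmse`, `fd`,
#'   `dtw`, `n_pairs`, `aggregation`.
#' @export
compare_sets <- function(real, generated,
                         aggregation = c("paired_mean", "nearest_real_mean")) {
  aggregation <- match.arg(aggregation)
  R <- if (inherits(real, "frame_set")) real$frames else as.matrix(real)
  G <- if (inherits(generated, "frame_set")) generated$frames
       else as.matrix(generated)
  if (nrow(R) == 0L || nrow(G) == 0L) stop("empty set")
  if (ncol(R) != ncol(G)) stop("frame length mismatch")
  if (aggregation == "paired_mean") {
    if (nrow(R) != nrow(G)) {
      stop("paired_mean requires equal frame counts")
    }
    vals <- vapply(seq_len(nrow(R)), function(i) {
      c(rmse(R[i, ], G[i, ]),
        frechet_distance(R[i, ], G[i, ]),
        dtw_distance(R[i, ], G[i, ]))
    }, numeric(3L))
    out <- rowMeans(vals)
    n_pairs <- nrow(R)
  } else {
    per_gen <- vapply(seq_len(nrow(G)), function(j) {
      best <- c(Inf, Inf, Inf)
      for (i in seq_len(nrow(R))) {
        best[1L] <- min(best[1L], rmse(R[i, ], G[j, ]))
        best[2L] <- min(best[2L], frechet_distance(R[i, ], G[j, ]))
        best[3L] <- min(best[3L], dtw_distance(R[i, ], G[j, ]))
      }
      best
    }, numeric(3L))
    out <- rowMeans(per_gen)
    n_pairs <- ncol(per_gen)
  }
  structure(list(rmse = out[1L], fd = out[2L], dtw = out[3L],
                 n_pairs = n_pairs, aggregation = aggregation),
            class = "metric_report")
}

#' @exportS3Method base::print
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %s over %d pairs: RMSE %.4f  FD %.4f  DTW %.4f\n",
              x$aggregation, x$n_pairs, x$rmse, x$fd, x$dtw))
  invisible(x)
}

#' Short-time power spectrum of a frame
#'
#' Power is normalized so that the summed power of each column equals the
#' energy of the corresponding windowed segment (Parseval); one-sided
#' bins, with the non-DC/non-Nyquist bins doubled.
#'
#' @param frame numeric vector.
#' @param sampling_rate Hz.
#' @param window window length in samples (<= frame length).
#' @param overlap overlap between consecutive windows in samples.
#' @param window_fn "hann" (default) or "rect".
#' @return list with `power` (freq x time matrix), `freq` (Hz), `time`
#'   (s, segment centers).
#' @export
spectrogram <- function(frame, sampling_rate, window = 128L,
                        overlap = window %/% 2L,
                        window_fn = c("hann", "rect")) {
  frame <- as.numeric(frame)
  window_fn <- match.arg(window_fn)
  L <- length(frame)
  if (window > L) stop("window larger than frame")
  stopifnot(overlap >= 0L, overlap < window)
  w <- if (window_fn == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq(0, window - 1L) / window)
  } else rep(1, window)
  hop <- window - overlap
  starts <- seq(1L, L - window + 1L, by = hop)
  nf <- window %/% 2L + 1L
  P <- matrix(0, nf, length(starts))
  for (k in seq_along(starts)) {
    seg <- frame[starts[k]:(starts[k] + window - 1L)] * w
    X <- stats::fft(seg)
    full <- Mod(X)^2 / window       # two-sided; sums to energy of seg
    half <- full[seq_len(nf)]
    if (window %% 2L == 0L) {
      half[2L:(nf - 1L)] <- 2 * half[2L:(nf - 1L)]
    } else {
      half[2L:nf] <- 2 * half[2L:nf]
    }
    P[, k] <- half
  }
  list(power = P,
       freq = (seq_len(nf) - 1L) * sampling_rate / window,
       time = (starts - 1L + window / 2) / sampling_rate)
}
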
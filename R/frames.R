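#' Raw single-channel recording
#'
#' Container for one raw signal trace prior to framing. Amplitudes are in
#' microvolts (or any consistent unit); the sampling rate defaults to the
#' 250 Hz of standard motor-imagery BCI recordings.
#'
#' @param samples numeric vector of samples; may contain NA/NaN.
#' @param sampling_rate sampling rate in Hz, > 0.
#' @param channel_id optional channel label.
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(samples, sampling_rate = 250, channel_id = "C1") {
  stopifnot(is.numeric(samples), length(sampling_rate) == 1L,
            sampling_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 channel_id = channel_id),
            class = "raw_recording")
}

#' Fixed-length frame set
#'
#' The unit of all training and evaluation: a matrix of signal frames
#' (one frame per row) together with the pooled normalization statistics
#' needed to undo the zero-mean / unit-variance transform.
#'
#' @param frames numeric matrix, frames in rows.
#' @param mean,std pooled statistics (filled in by [normalize_frames()]).
#' @param normalized logical flag.
#' @return an object of class `frame_set`.
#' @export
frame_set <- function(frames, mean = NA_real_, std = NA_real_,
                      normalized = FALSE) {
  frames <- as.matrix(frames)
  structure(list(frames = frames, frame_len = ncol(frames),
                 mean = mean, std = std, normalized = normalized),
            class = "frame_set")
}

#' @exportS3Method base::print
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames x %d samples%s\n",
              nrow(x$frames), x$frame_len,
              if (isTRUE(x$normalized))
                sprintf(" (normalized; mean=%.4g, sd=%.4g)", x$mean, x$std)
              else ""))
  invisible(x)
}

#' @export
dim.frame_set <- function(x) dim(x$frames)

#' Replace missing samples by the minimum valid sample
#'
#' NaN/NA entries are replaced with the minimum of the non-missing values;
#' valid samples are left untouched. Idempotent.
#'
#' @param recording a [raw_recording()] or numeric vector.
#' @return object of the same type with no missing values.
#' @export
clean_nans <- function(recording) UseMethod("clean_nans")

#' @export
clean_nans.raw_recording <- function(recording) {
  recording$samples <- clean_nans(recording$samples)
  recording
}

#' @export
clean_nans.numeric <- function(recording) {
  bad <- is.na(recording)
  if (all(bad)) stop("no valid samples")
  if (any(bad)) recording[bad] <- min(recording[!bad])
  recording
}

#' Cut a recording into consecutive non-overlapping frames
#'
#' Frames are contiguous and time-ordered; a trailing remainder shorter
#' than `frame_len` is discarded. With the default 250 Hz sampling rate a
#' 500-sample frame spans 2 s.
#'
#' @param recording a [raw_recording()] or numeric vector.
#' @param frame_len frame length in samples (default 500).
#' @return a [frame_set()].
#' @export
segment_frames <- function(recording, frame_len = 500L) {
  stopifnot(frame_len >= 1L)
  x <- if (inherits(recording, "raw_recording")) recording$samples
       else as.numeric(recording)
  n <- floor(length(x) / frame_len)
  if (n == 0L) {
    warning("recording shorter than one frame; returning empty frame set")
    return(frame_set(matrix(numeric(0), 0L, frame_len)))
  }
  m <- matrix(x[seq_len(n * frame_len)], nrow = n, ncol = frame_len,
              byrow = TRUE)
  frame_set(m)
}

#' Pooled zero-mean / unit-variance normalization
#'
#' One global mean and (population) standard deviation are computed over
#' every entry of the set and stored for the inverse transform.
#'
#' @param fs a [frame_set()].
#' @return normalized [frame_set()] with `mean`/`std` recorded.
#' @export
normalize_frames <- function(fs) {
  stopifnot(inherits(fs, "frame_set"), nrow(fs$frames) > 0L)
  mu <- mean(fs$frames)
  sd_pop <- sqrt(mean((fs$frames - mu)^2))
  if (sd_pop <= 0) stop("constant signal")
  frame_set((fs$frames - mu) / sd_pop, mean = mu, std = sd_pop,
            normalized = TRUE)
}

#' Undo [normalize_frames()]
#' @param fs a normalized [frame_set()].
#' @return [frame_set()] on the original scale.
#' @export
denormalize_frames <- function(fs) {
  stopifnot(isTRUE(fs$normalized))
  frame_set(fs$frames * fs$std + fs$mean)
}

round_half_up <- function(x) floor(x + 0.5)

#' Seeded random train/test split
#'
#' Frames are shuffled with a pseudorandom seed and partitioned so that
#' `|train| = round(train_fraction * n)` (half-up). One permutation is
#' drawn per seed; the majority block is read from its head, so fractions
#' f and 1-f with the same seed yield the same partition with the roles
#' of train and test exchanged.
#'
#' @param fs a [frame_set()] with at least 2 frames.
#' @param train_fraction proportion in (0, 1); default 0.7.
#' @param seed integer seed.
#' @return list with `train` and `test` frame sets and the index vectors.
#' @export
split_frames <- function(fs, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(fs, "frame_set"), nrow(fs$frames) >= 2L,
            train_fraction > 0, train_fraction < 1)
  n <- nrow(fs$frames)
  k <- as.integer(round_half_up(train_fraction * n))
  k <- max(1L, min(n - 1L, k))
  perm <- with_seed(seed, sample.int(n))
  if (train_fraction >= 0.5) {
    tr <- perm[seq_len(k)]
    te <- perm[(k + 1L):n]
  } else {
    te <- perm[seq_len(n - k)]
    tr <- perm[(n - k + 1L):n]
  }
  mk <- function(idx) frame_set(fs$frames[idx, , drop = FALSE],
                                mean = fs$mean, std = fs$std,
                                normalized = fs$normalized)
  list(train = mk(tr), test = mk(te), train_idx = tr, test_idx = te)
}
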
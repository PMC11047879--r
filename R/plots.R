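# Cosmetic plotting helpers (base graphics).

#' Plot the critic/generator loss curves of a training run
#' @param history history data.frame from [train_gan()].
#' @param file optional PNG path; NULL plots to the active device.
#' @export
plot_loss_history <- function(history, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 500)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(history$epoch, history$d_loss, type = "l", col = "#1f77b4",
                 xlab = "epoch", ylab = "loss", main = "Adversarial training")
  ok <- is.finite(history$g_loss)
  graphics::lines(history$epoch[ok], history$g_loss[ok], col = "#d62728")
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", c("critic", "generator"), lty = 1,
                   col = c("#1f77b4", "#d62728"), bty = "n")
  invisible(NULL)
}

#' Overlay real and generated frames in the time domain
#' @param real,generated [frame_set()]s; the first `n` frames are drawn.
#' @param n frames to overlay (default 3).
#' @param sampling_rate Hz, for the time axis.
#' @param file optional PNG path.
#' @export
plot_frames_overlay <- function(real, generated, n = 3L,
                                sampling_rate = 250, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 300 * n)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(n, 1L), mar = c(3, 3, 1, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (i in seq_len(n)) {
    tt <- (seq_len(ncol(real$frames)) - 1L) / sampling_rate
    graphics::plot(tt, real$frames[i, ], type = "l", col = "#d62728",
                   xlab = "time (s)", ylab = "amplitude")
    graphics::lines(tt, generated$frames[i, ], col = "#7f3fbf")
  }
  invisible(NULL)
}
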
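#' Plot a recording's signal and power spectral density
#'
#' Two-panel base-graphics view of one 3-axis recording: the time-domain
#' traces and the Welch PSD per axis. A rest tremor shows up as a sharp
#' spectral peak in the 4-6 Hz band.
#'
#' @param x An `assessment_recording`.
#' @param f_max Upper frequency (Hz) shown in the PSD panel.
#' @param ... Passed to `matplot()`.
#' @return Invisibly, `x`.
#' @export
plot.assessment_recording <- function(x, f_max = 20, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  t <- (seq_len(nrow(x$samples)) - 1L) / x$fs
  graphics::matplot(t, x$samples, type = "l", lty = 1, xlab = "time [s]",
                    ylab = "signal", main = paste(x$step, x$wrist, x$sensor),
                    ...)
  psd <- sapply(1:3, function(a) welch_psd(x$samples[, a], x$fs)$psd)
  freq <- welch_psd(x$samples[, 1], x$fs)$freq
  keep <- freq > 0 & freq <= f_max
  graphics::matplot(freq[keep], log10(psd[keep, ] + 1e-12), type = "l",
                    lty = 1, xlab = "frequency [Hz]",
                    ylab = "log10 PSD", main = "Welch PSD")
  invisible(x)
}

#' Bar chart of grouped permutation importances
#'
#' @param x A `group_importance`.
#' @param top Number of top groups shown.
#' @param ... Passed to `barplot()`.
#' @return Invisibly, `x`.
#' @export
plot.group_importance <- function(x, top = 10, ...) {
  r <- utils::head(rank_groups(x), top)
  graphics::barplot(rev(r$mean_drop), names.arg = rev(r$group), horiz = TRUE,
                    las = 1, xlab = "balanced-accuracy drop", ...)
  invisible(x)
}
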
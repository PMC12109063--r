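#' Plot a fatigue trajectory
#'
#' Shows the fitted MF line against time with the dashed level boundaries of
#' the calibrated range, and the resulting stepped fatigue level LF on a
#' secondary axis. Optionally overlays the per-window MF observations.
#'
#' @param x A [fatigue_trajectory()].
#' @param mf Optional [mf_series] of the same session, drawn as points.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.fatigue_trajectory <- function(x, mf = NULL, ...) {
  smfdr <- attr(x, "smfdr")
  N <- attr(x, "N")
  bounds <- level_boundaries(smfdr, N)
  ylim <- range(c(x$y_i_hz, bounds$lower_hz, bounds$upper_hz,
                  if (!is.null(mf)) mf$mf_hz))
  op <- par(mar = c(4.5, 4.5, 2, 4.5))
  on.exit(par(op))
  plot(x$time_s, x$y_i_hz, type = "l", col = "blue", lwd = 2,
       xlab = "time (s)", ylab = "median frequency (Hz)", ylim = ylim,
       main = sprintf("Fatigue trajectory (N = %d)", N))
  if (!is.null(mf)) points(mf$time_s, mf$mf_hz, pch = 16, cex = 0.6,
                           col = "grey40")
  abline(h = bounds$lower_hz[-N], lty = 2, col = "grey55")
  # LF step curve rescaled onto the frequency axis
  lf_y <- ylim[1] + x$LF * diff(ylim)
  lines(x$time_s, lf_y, type = "s", col = "red", lwd = 2)
  axis(4, at = ylim[1] + seq(0, 1, by = 0.25) * diff(ylim),
       labels = sprintf("%.2f", seq(0, 1, by = 0.25)), col.axis = "red")
  mtext("fatigue level LF", side = 4, line = 2.8, col = "red")
  legend("bottomleft", bty = "n", lwd = 2, lty = c(1, 1, 2),
         col = c("blue", "red", "grey55"),
         legend = c("fitted MF", "fatigue level", "level boundaries"))
  invisible(x)
}
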
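#' Draw a rose histogram
#'
#' Simple base-graphics renderer for a [rose_histogram()]: one wedge
#' per bin, radius proportional to count, mean direction drawn as a
#' radial line.
#'
#' @param x A `rose_histogram`.
#' @param col Fill colour for the wedges.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot_rose <- function(x, col = "#d0649688", ...) {
  r <- if (max(x$counts) > 0) x$counts / max(x$counts) else x$counts
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", ...)
  for (k in seq_len(x$n_bins)) {
    th <- seq(x$bin_edges_deg[k], x$bin_edges_deg[k + 1],
              length.out = 16) * pi / 180
    graphics::polygon(c(0, r[k] * cos(th)), c(0, r[k] * sin(th)),
                      col = col, border = "grey30")
  }
  if (!is.na(x$mean_dir_deg)) {
    th <- x$mean_dir_deg * pi / 180
    graphics::segments(0, 0, cos(th), sin(th), lwd = 2)
  }
  invisible(x)
}

#' Draw the main sequence
#'
#' Amplitude vs. peak velocity on log-log axes.
#'
#' @param pairs Data frame from [main_sequence()].
#' @param ... Passed to [graphics::plot()].
#' @return `pairs`, invisibly.
#' @export
plot_main_sequence <- function(pairs, ...) {
  graphics::plot(pairs$amplitude, pairs$peak_velocity, log = "xy",
                 xlab = "amplitude (deg)", ylab = "peak velocity (deg/s)",
                 pch = 20, col = "#00000066", ...)
  invisible(pairs)
}

#' Draw a temporal-position histogram
#'
#' @param h Data frame from [temporal_histogram()].
#' @param ... Passed to [graphics::barplot()].
#' @return `h`, invisibly.
#' @export
plot_temporal_histogram <- function(h, ...) {
  graphics::barplot(h$count, names.arg = h$bin_start_ms,
                    xlab = "onset within fixation (ms)", ylab = "count", ...)
  invisible(h)
}
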
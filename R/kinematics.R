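#' Convert a pixel trace to visual degrees
#'
#' Maps screen-pixel coordinates to visual angle about the screen
#' centre, per axis: `theta = atan((p - c) * mm_per_px / distance)` in
#' degrees, where `c` is the screen centre in pixels.  This assumes the
#' eye is on the screen-centre normal at a fixed viewing distance.
#'
#' @param trace A [gaze_trace()] with `unit = "px"`.
#' @param geometry A [viewing_geometry()].
#' @return The trace with coordinates in degrees and `unit = "deg"`.
#' @export
pixels_to_degrees <- function(trace, geometry) {
  if (trace$unit != "px") {
    stop("trace is not in pixel units", call. = FALSE)
  }
  if (is.null(geometry)) {
    stop("viewing geometry is required to convert pixels to visual degrees; ",
         "supply viewing_geometry(distance_mm, screen_px, screen_mm)",
         call. = FALSE)
  }
  mmpp <- geometry$screen_mm / geometry$screen_px
  cx <- geometry$screen_px[1] / 2
  cy <- geometry$screen_px[2] / 2
  deg <- function(p, c, m) atan((p - c) * m / geometry$distance_mm) * 180 / pi
  out <- trace
  out$x <- deg(trace$x, cx, mmpp[1])
  out$y <- deg(trace$y, cy, mmpp[2])
  out$unit <- "deg"
  out
}

#' Estimate gaze velocity with a weighted central-difference stencil
#'
#' For an odd window `w = 2m + 1`, velocity at sample `n` is
#' `v_n = sum_{k=1..m} (x_{n+k} - x_{n-k}) / (2 * dt * sum_{k=1..m} k)`.
#' For `w = 5` this reduces to the classic 5-sample stencil
#' `(x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2}) / (6 dt)`.  The stencil is
#' exact for affine trajectories at any window size.
#'
#' Velocity is undefined (mask `FALSE`) wherever the stencil touches a
#' trace edge or an invalid sample; samples near gaps are masked rather
#' than interpolated.
#'
#' @param trace A [gaze_trace()] (degrees recommended; units are
#'   carried through unchanged per second).
#' @param window_samples Odd integer >= 3, the velocity window size.
#' @return A list of class `velocity_series`: `vx`, `vy`, `speed`
#'   (`sqrt(vx^2 + vy^2)`) per sample, and logical `defined`.
#' @export
estimate_velocity <- function(trace, window_samples = 5L) {
  w <- as.integer(window_samples)
  n <- length(trace$x)
  if (w < 3L || w %% 2L == 0L) {
    stop("velocity window must be an odd integer >= 3", call. = FALSE)
  }
  if (w > n) {
    stop("velocity window exceeds trace length", call. = FALSE)
  }
  m <- (w - 1L) %/% 2L
  dt <- 1 / trace$rate_hz
  denom <- 2 * dt * sum(seq_len(m))
  vx <- rep(NA_real_, n)
  vy <- rep(NA_real_, n)
  core <- (m + 1L):(n - m)
  sx <- numeric(length(core))
  sy <- numeric(length(core))
  for (k in seq_len(m)) {
    sx <- sx + (trace$x[core + k] - trace$x[core - k])
    sy <- sy + (trace$y[core + k] - trace$y[core - k])
  }
  vx[core] <- sx / denom
  vy[core] <- sy / denom
  # stencil must not touch any invalid sample
  ok <- trace$valid
  win_ok <- rep(TRUE, length(core))
  for (k in -m:m) {
    win_ok <- win_ok & ok[core + k]
  }
  defined <- rep(FALSE, n)
  defined[core] <- win_ok
  vx[!defined] <- NA_real_
  vy[!defined] <- NA_real_
  structure(
    list(vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2), defined = defined,
         window = w, rate_hz = trace$rate_hz),
    class = "velocity_series"
  )
}

#' Median-based robust velocity dispersion
#'
#' Per axis, `sigma = sqrt(median(v^2) - median(v)^2)` over the defined
#' samples in scope — a median-based analogue of the standard deviation
#' that is insensitive to the rare high-velocity samples the threshold
#' is meant to find.
#'
#' @param vel A `velocity_series` from [estimate_velocity()].
#' @param scope_idx Optional integer vector of sample indices to pool
#'   (e.g. all fixation samples of a trial); default all samples.
#' @return Named numeric vector `c(sigma_x, sigma_y)` in velocity units.
#' @export
robust_sigma <- function(vel, scope_idx = NULL) {
  keep <- vel$defined
  if (!is.null(scope_idx)) {
    sel <- rep(FALSE, length(keep))
    sel[scope_idx] <- TRUE
    keep <- keep & sel
  }
  if (sum(keep) < 10L) {
    stop("fewer than 10 defined velocity samples in scope", call. = FALSE)
  }
  sig <- function(v) {
    s2 <- stats::median(v^2) - stats::median(v)^2
    sqrt(max(s2, 0))
  }
  sx <- sig(vel$vx[keep])
  sy <- sig(vel$vy[keep])
  if (sx < 1e-10 || sy < 1e-10) {
    stop("degenerate velocity signal: robust dispersion below 1e-10 deg/s ",
         "(constant or duplicated data?)", call. = FALSE)
  }
  c(sigma_x = sx, sigma_y = sy)
}
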
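# Small builders used across test files.

# quiet trace with optional injected events; deterministic, no RNG
flat_trace <- function(n, rate = 500, eye = "right", jitter = 0.002) {
  # tiny deterministic wiggle keeps the dispersion estimator non-degenerate
  i <- seq_len(n)
  x <- jitter * sin(i * 0.7) + 1e-4 * sin(i * 2.3)
  y <- jitter * cos(i * 1.1) + 1e-4 * cos(i * 1.9)
  gaze_trace(x, y, rate, unit = "deg", eye = eye)
}

# add a raised-cosine step of given displacement over [onset, offset)
inject_step <- function(trace, onset, offset, dx, dy) {
  len <- offset - onset
  frac <- function(tau) tau - sin(2 * pi * tau) / (2 * pi)
  prof <- frac(seq_len(len) / len)
  n <- length(trace$x)
  j <- onset:(offset - 1)
  trace$x[j] <- trace$x[j] + dx * prof
  trace$y[j] <- trace$y[j] + dy * prof
  if (offset <= n) {
    trace$x[offset:n] <- trace$x[offset:n] + dx
    trace$y[offset:n] <- trace$y[offset:n] + dy
  }
  trace
}

one_fixation <- function(trace) {
  msdetect:::fixation_table(trace, 1L, length(trace$x) + 1L)
}

# velocity_series stub for direct robust_sigma/threshold tests
fake_vel <- function(vx, vy = vx, defined = NULL) {
  if (is.null(defined)) defined <- rep(TRUE, length(vx))
  structure(list(vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2),
                 defined = defined, window = 3L, rate_hz = 500),
            class = "velocity_series")
}

# short synthetic config for fast cohort tests
short_sim_config <- function(...) {
  sim_config(trial_s = 3, fix_dur_range_s = c(0.5, 1.0), ...)
}
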
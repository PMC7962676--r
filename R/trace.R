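#' Construct a gaze trace
#'
#' A gaze trace is one eye's uniformly sampled position time series.
#' Timestamps are represented internally as sample index over sampling
#' rate (plus a trial start time), so times are exact and round-trip
#' through text files without drift.
#'
#' @param x,y Numeric vectors of horizontal/vertical gaze position.
#'   Screen convention: origin top-left, y increases downward.
#' @param rate_hz Sampling frequency in Hz.  Rates below 200 Hz trigger a
#'   warning: microsaccades (durations down to ~6 ms) are not reliably
#'   resolvable at lower rates.
#' @param unit Coordinate unit, `"px"` or `"deg"`.
#' @param eye Which eye the trace belongs to: `"left"`, `"right"` or
#'   `"averaged"`.
#' @param valid Logical vector flagging usable samples; invalid samples
#'   open missing-data gaps.
#' @param t0 Time of the first sample in seconds.
#'
#' @return An object of class `gaze_trace`: a list with fields `x`, `y`,
#'   `valid`, `rate_hz`, `unit`, `eye`, `t0`.
#' @export
gaze_trace <- function(x, y, rate_hz, unit = c("deg", "px"),
                       eye = c("right", "left", "averaged"),
                       valid = NULL, t0 = 0) {
  unit <- match.arg(unit)
  eye <- match.arg(eye)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (is.null(valid)) {
    valid <- is.finite(x) & is.finite(y)
  }
  valid <- as.logical(valid) & is.finite(x) & is.finite(y)
  if (length(valid) != length(x)) {
    stop("valid must match the sample count", call. = FALSE)
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1 || rate_hz <= 0) {
    stop("rate_hz must be a positive scalar", call. = FALSE)
  }
  if (rate_hz < 200) {
    warning("sampling rate below 200 Hz; microsaccade detection is unreliable",
            call. = FALSE)
  }
  structure(
    list(x = x, y = y, valid = valid, rate_hz = rate_hz,
         unit = unit, eye = eye, t0 = t0),
    class = "gaze_trace"
  )
}

#' @export
length.gaze_trace <- function(x) length(x$x)

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("<gaze_trace> eye=%s  n=%d  rate=%g Hz  unit=%s  missing=%d samples\n",
              x$eye, length(x$x), x$rate_hz, x$unit, sum(!x$valid)))
  invisible(x)
}

#' Sample timestamps of a trace
#'
#' @param trace A [gaze_trace()].
#' @return Numeric vector of timestamps in seconds, `t0 + (i-1)/rate`.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$x) - 1) / trace$rate_hz
}

#' Missing-data ranges of a trace
#'
#' Consecutive invalid samples coalesce into one gap.
#'
#' @param trace A [gaze_trace()].
#' @return Data frame with columns `onset`, `offset` — 1-based half-open
#'   sample-index intervals (sorted, disjoint) — and `onset_t`,
#'   `offset_t` in seconds.
#' @export
missing_ranges <- function(trace) {
  runs <- index_runs(which(!trace$valid))
  runs$onset_t <- trace$t0 + (runs$onset - 1) / trace$rate_hz
  runs$offset_t <- trace$t0 + (runs$offset - 1) / trace$rate_hz
  runs
}

# maximal runs of consecutive indices -> half-open [onset, offset) intervals
index_runs <- function(idx) {
  if (length(idx) == 0) {
    return(data.frame(onset = integer(0), offset = integer(0)))
  }
  idx <- sort(unique(as.integer(idx)))
  brk <- which(diff(idx) > 1L)
  starts <- idx[c(1L, brk + 1L)]
  ends <- idx[c(brk, length(idx))]
  data.frame(onset = starts, offset = ends + 1L)
}

#' Average the two eyes' traces
#'
#' Produces the cyclopean ("averaged") trace as the sample-wise mean of
#' left and right eye positions.  A sample is valid only where both eyes
#' are valid.
#'
#' @param left,right [gaze_trace()] objects with identical length,
#'   sampling rate, unit and start time.
#' @return A `gaze_trace` with `eye = "averaged"`.
#' @export
average_eyes <- function(left, right) {
  if (length(left$x) != length(right$x)) {
    stop("left and right traces differ in length", call. = FALSE)
  }
  if (left$rate_hz != right$rate_hz || left$unit != right$unit ||
      left$t0 != right$t0) {
    stop("left and right traces differ in rate, unit or start time",
         call. = FALSE)
  }
  gaze_trace(
    x = (left$x + right$x) / 2,
    y = (left$y + right$y) / 2,
    rate_hz = left$rate_hz,
    unit = left$unit,
    eye = "averaged",
    valid = left$valid & right$valid,
    t0 = left$t0
  )
}

#' Construct a trial
#'
#' A trial bundles the per-eye traces of one recording interval together
#' with optional precomputed fixations and microsaccades (as interval
#' tables) and event markers.
#'
#' @param trial_id Character trial identifier.
#' @param traces Named list of [gaze_trace()] objects; names among
#'   `"left"`, `"right"`, `"averaged"`.
#' @param participant_id Character participant identifier.
#' @param condition Optional test-condition label (`NA` if none).
#' @param fixations,microsaccades Optional precomputed interval tables
#'   (data frames with at least `onset`, `offset` in 1-based half-open
#'   sample indices, and an `eye` column).
#' @param event_markers Optional data frame with columns `t` (seconds)
#'   and `label`.
#' @return An object of class `gaze_trial`.
#' @export
gaze_trial <- function(trial_id, traces, participant_id = NA_character_,
                       condition = NA_character_, fixations = NULL,
                       microsaccades = NULL, event_markers = NULL) {
  if (!is.list(traces) || length(traces) == 0 || is.null(names(traces))) {
    stop("traces must be a non-empty named list", call. = FALSE)
  }
  bad <- setdiff(names(traces), c("left", "right", "averaged"))
  if (length(bad)) {
    stop("unknown eye label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ns <- vapply(traces, function(tr) length(tr$x), integer(1))
  if (length(unique(ns)) != 1) {
    stop("all traces of a trial must have equal length", call. = FALSE)
  }
  n <- ns[[1]]
  check_intervals <- function(df, what) {
    if (is.null(df)) return(invisible())
    if (nrow(df) && (any(df$onset < 1) || any(df$offset > n + 1L))) {
      stop(what, " intervals lie outside the trace span", call. = FALSE)
    }
  }
  check_intervals(fixations, "fixation")
  check_intervals(microsaccades, "microsaccade")
  if (is.null(event_markers)) {
    event_markers <- data.frame(t = numeric(0), label = character(0))
  }
  structure(
    list(trial_id = as.character(trial_id),
         participant_id = as.character(participant_id),
         condition = as.character(condition),
         traces = traces,
         fixations = fixations,
         microsaccades = microsaccades,
         event_markers = event_markers),
    class = "gaze_trial"
  )
}

#' @export
print.gaze_trial <- function(x, ...) {
  cat(sprintf("<gaze_trial> %s (participant %s, condition %s): eyes [%s], %d samples\n",
              x$trial_id, x$participant_id, x$condition,
              paste(names(x$traces), collapse = ","),
              length(x$traces[[1]]$x)))
  invisible(x)
}

#' Pick a trace from a trial by eye mode
#'
#' For `"averaged"` the cyclopean trace is computed on the fly from left
#' and right if not stored.
#'
#' @param trial A [gaze_trial()].
#' @param eye `"left"`, `"right"` or `"averaged"`.
#' @return A [gaze_trace()].
#' @export
trial_trace <- function(trial, eye) {
  if (!is.null(trial$traces[[eye]])) {
    return(trial$traces[[eye]])
  }
  if (eye == "averaged" &&
      !is.null(trial$traces$left) && !is.null(trial$traces$right)) {
    return(average_eyes(trial$traces$left, trial$traces$right))
  }
  stop("trial ", trial$trial_id, " has no '", eye, "' eye data", call. = FALSE)
}

#' Viewing geometry for pixel-to-degree conversion
#'
#' @param distance_mm Eye-to-screen viewing distance in millimetres.
#' @param screen_px Integer vector `c(width, height)` in pixels.
#' @param screen_mm Numeric vector `c(width, height)` in millimetres.
#' @return An object of class `viewing_geometry`.
#' @export
viewing_geometry <- function(distance_mm, screen_px, screen_mm) {
  if (any(c(distance_mm, screen_px, screen_mm) <= 0) ||
      length(screen_px) != 2 || length(screen_mm) != 2) {
    stop("viewing geometry requires positive distance and 2-vector screen sizes",
         call. = FALSE)
  }
  structure(list(distance_mm = distance_mm,
                 screen_px = as.numeric(screen_px),
                 screen_mm = as.numeric(screen_mm)),
            class = "viewing_geometry")
}
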
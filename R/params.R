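#' Microsaccade filter parameters
#'
#' Defaults follow the common literature configuration for 500 Hz
#' binocular recordings: threshold multiplier `lambda = 5`, minimum
#' duration 6 ms, velocity window 5 samples, maximum amplitude 1 deg,
#' minimum inter-saccadic interval 20 ms, first 20 ms of each fixation
#' ignored (glissade exclusion), binocular detection.
#'
#' @param lambda Unitless multiplier applied to the robust velocity
#'   dispersion to form the elliptic 2D velocity threshold.
#' @param min_dur_ms,max_dur_ms Event duration bounds in ms.
#' @param min_amp_deg,max_amp_deg Amplitude bounds in degrees.
#' @param min_pv_degs,max_pv_degs Peak-velocity bounds in deg/s.
#' @param vel_window Velocity window size in samples (odd, >= 3).
#' @param ignore_fix_start_ms,ignore_fix_end_ms Time ignored at the
#'   beginning/end of each fixation (the start window suppresses
#'   post-saccadic glissades).
#' @param min_isi_ms Minimum inter-saccadic interval: an event starting
#'   less than this after the previous kept event's offset is discarded
#'   (suppresses overshoot artifacts).
#' @param ignore_around_missing_ms Time ignored before/after missing
#'   data gaps.
#' @param eye_mode `"binocular"`, `"left"`, `"right"` or `"averaged"`.
#'   Binocular detection runs both eyes and keeps only temporally
#'   overlapping pairs, merged into single events.
#' @param sigma_scope `"trial"` pools all fixation samples of a trial
#'   for the dispersion estimate; `"fixation"` estimates it per
#'   fixation.
#' @return An object of class `ms_params`.
#' @export
microsaccade_params <- function(lambda = 5, min_dur_ms = 6, max_dur_ms = Inf,
                                min_amp_deg = 0, max_amp_deg = 1,
                                min_pv_degs = 0, max_pv_degs = Inf,
                                vel_window = 5L,
                                ignore_fix_start_ms = 20,
                                ignore_fix_end_ms = 0,
                                min_isi_ms = 20,
                                ignore_around_missing_ms = 0,
                                eye_mode = c("binocular", "left", "right",
                                             "averaged"),
                                sigma_scope = c("trial", "fixation")) {
  p <- list(lambda = lambda, min_dur_ms = min_dur_ms, max_dur_ms = max_dur_ms,
            min_amp_deg = min_amp_deg, max_amp_deg = max_amp_deg,
            min_pv_degs = min_pv_degs, max_pv_degs = max_pv_degs,
            vel_window = as.integer(vel_window),
            ignore_fix_start_ms = ignore_fix_start_ms,
            ignore_fix_end_ms = ignore_fix_end_ms,
            min_isi_ms = min_isi_ms,
            ignore_around_missing_ms = ignore_around_missing_ms,
            eye_mode = match.arg(eye_mode),
            sigma_scope = match.arg(sigma_scope))
  validate_params(p)
  structure(p, class = "ms_params")
}

#' Saccade filter parameters
#'
#' The saccade filter runs the same velocity-threshold pipeline over the
#' whole trial (no fixation windows) with its own defaults:
#' `lambda = 8`, minimum duration 3 ms, window 9 samples, minimum
#' amplitude 1 deg, minimum inter-saccadic interval 50 ms.  The 1 deg
#' minimum amplitude suppresses fixational events; fixations are then
#' the intervals between detected saccades.
#'
#' @inheritParams microsaccade_params
#' @return An object of class `sacc_params`.
#' @export
saccade_params <- function(lambda = 8, min_dur_ms = 3, max_dur_ms = Inf,
                           min_amp_deg = 1, max_amp_deg = Inf,
                           min_pv_degs = 0, max_pv_degs = Inf,
                           vel_window = 9L, min_isi_ms = 50,
                           ignore_around_missing_ms = 0) {
  p <- list(lambda = lambda, min_dur_ms = min_dur_ms, max_dur_ms = max_dur_ms,
            min_amp_deg = min_amp_deg, max_amp_deg = max_amp_deg,
            min_pv_degs = min_pv_degs, max_pv_degs = max_pv_degs,
            vel_window = as.integer(vel_window),
            ignore_fix_start_ms = 0, ignore_fix_end_ms = 0,
            min_isi_ms = min_isi_ms,
            ignore_around_missing_ms = ignore_around_missing_ms)
  validate_params(p)
  structure(p, class = "sacc_params")
}

validate_params <- function(p) {
  if (!is.numeric(p$lambda) || p$lambda <= 0) {
    stop("lambda must be positive", call. = FALSE)
  }
  if (p$vel_window < 3L || p$vel_window %% 2L == 0L) {
    stop("vel_window must be an odd integer >= 3", call. = FALSE)
  }
  nn <- c("min_dur_ms", "min_amp_deg", "min_pv_degs", "ignore_fix_start_ms",
          "ignore_fix_end_ms", "min_isi_ms", "ignore_around_missing_ms")
  for (f in nn) {
    if (p[[f]] < 0) stop(f, " must be non-negative", call. = FALSE)
  }
  if (p$min_dur_ms > p$max_dur_ms || p$min_amp_deg > p$max_amp_deg ||
      p$min_pv_degs > p$max_pv_degs) {
    stop("lower bounds must not exceed upper bounds", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.ms_params <- function(x, ...) {
  cat("<microsaccade filter>\n")
  cat(sprintf("  lambda=%g  window=%d samples  duration=[%g,%g] ms\n",
              x$lambda, x$vel_window, x$min_dur_ms, x$max_dur_ms))
  cat(sprintf("  amplitude=[%g,%g] deg  peak velocity=[%g,%g] deg/s\n",
              x$min_amp_deg, x$max_amp_deg, x$min_pv_degs, x$max_pv_degs))
  cat(sprintf("  ignore fixation start/end=%g/%g ms  min ISI=%g ms  near-gap=%g ms\n",
              x$ignore_fix_start_ms, x$ignore_fix_end_ms, x$min_isi_ms,
              x$ignore_around_missing_ms))
  cat(sprintf("  eye mode=%s  sigma scope=%s\n", x$eye_mode, x$sigma_scope))
  invisible(x)
}

#' @export
print.sacc_params <- function(x, ...) {
  cat("<saccade filter>\n")
  cat(sprintf("  lambda=%g  window=%d samples  duration=[%g,%g] ms  amplitude=[%g,%g] deg\n",
              x$lambda, x$vel_window, x$min_dur_ms, x$max_dur_ms,
              x$min_amp_deg, x$max_amp_deg))
  cat(sprintf("  min ISI=%g ms  near-gap=%g ms\n",
              x$min_isi_ms, x$ignore_around_missing_ms))
  invisible(x)
}
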
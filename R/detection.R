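#' @keywords internal
empty_events <- function() {
  data.frame(
    kind = character(0), eye = character(0),
    onset = integer(0), offset = integer(0),
    onset_t = numeric(0), offset_t = numeric(0), duration_ms = numeric(0),
    dx = numeric(0), dy = numeric(0),
    amp_x = numeric(0), amp_y = numeric(0), amplitude = numeric(0),
    peak_velocity = numeric(0), direction_deg = numeric(0),
    fixation_id = integer(0), t_in_fixation_ms = numeric(0),
    onset_left = integer(0), offset_left = integer(0),
    onset_right = integer(0), offset_right = integer(0),
    stringsAsFactors = FALSE
  )
}

# direction of screen-space displacement (y grows downward):
# 0 deg = rightward, 90 deg = up on screen, counter-clockwise positive.
screen_direction_deg <- function(dx, dy) {
  (atan2(-dy, dx) * 180 / pi) %% 360
}

#' Super-threshold candidate intervals
#'
#' Maximal runs of samples whose velocity lies strictly outside the
#' elliptic threshold `(vx/(lambda*sigma_x))^2 + (vy/(lambda*sigma_y))^2
#' > 1` and whose velocity is defined.  Runs never bridge masked
#' samples.  Runs shorter than `min_dur_samples` are dropped.
#'
#' @param vel A `velocity_series`.
#' @param sigma Numeric `c(sigma_x, sigma_y)` from [robust_sigma()].
#' @param lambda Threshold multiplier.
#' @param min_dur_samples Minimum run length in samples.
#' @param scope Optional integer vector of sample indices to restrict
#'   the scan to (e.g. one fixation's span).
#' @return Data frame with `onset`, `offset` (1-based, half-open).
#' @export
threshold_candidates <- function(vel, sigma, lambda, min_dur_samples = 1L,
                                 scope = NULL) {
  if (any(sigma <= 0)) {
    stop("sigma must be positive", call. = FALSE)
  }
  r2 <- (vel$vx / (lambda * sigma[[1]]))^2 + (vel$vy / (lambda * sigma[[2]]))^2
  hit <- !is.na(r2) & vel$defined & r2 > 1
  idx <- which(hit)
  if (!is.null(scope)) {
    idx <- idx[idx %in% scope]
  }
  runs <- index_runs(idx)
  runs[(runs$offset - runs$onset) >= min_dur_samples, , drop = FALSE]
}

# kinematics of one event interval [onset, offset) on a trace.
# amp_x/amp_y are sign-carrying coordinate ranges (sign = temporal order
# of the extrema); amplitude = sqrt(amp_x^2 + amp_y^2); direction from
# the start-to-end displacement.
event_kinematics <- function(trace, vel, onset, offset) {
  i <- onset:(offset - 1L)
  x <- trace$x[i]
  y <- trace$y[i]
  dx <- x[length(x)] - x[1]
  dy <- y[length(y)] - y[1]
  sgn <- function(v) {
    s <- sign(which.max(v) - which.min(v))
    if (s == 0) 1 else s
  }
  amp_x <- sgn(x) * (max(x) - min(x))
  amp_y <- sgn(y) * (max(y) - min(y))
  sp <- vel$speed[i]
  pv <- if (all(is.na(sp))) NA_real_ else max(sp, na.rm = TRUE)
  list(dx = dx, dy = dy, amp_x = amp_x, amp_y = amp_y,
       amplitude = sqrt(amp_x^2 + amp_y^2),
       peak_velocity = pv,
       direction_deg = screen_direction_deg(dx, dy))
}

#' Apply the extended event constraints to candidate intervals
#'
#' In order: (1) drop candidates overlapping the ignored start/end
#' windows of the fixation (overlap means drop, never trim — a trimmed
#' glissade fragment is not a microsaccade); (2) drop candidates within
#' `ignore_around_missing_ms` of a missing-data gap; (3) compute
#' kinematics and drop events violating duration / amplitude /
#' peak-velocity bounds; (4) scan left to right discarding any event
#' whose onset is less than `min_isi_ms` after the previous kept
#' event's offset.
#'
#' @param candidates Data frame from [threshold_candidates()].
#' @param trace The [gaze_trace()] the candidates refer to.
#' @param vel The `velocity_series` used for detection.
#' @param params `ms_params` or `sacc_params`.
#' @param fixation Optional one-row fixation (list or data-frame row
#'   with `onset`, `offset`, `fixation_id`); when given, fixation-scoped
#'   constraints apply and events carry the fixation id and onset time
#'   within the fixation.
#' @param kind Event label, `"microsaccade"` or `"saccade"`.
#' @return Event data frame (see [detect_microsaccades()]).
#' @export
apply_constraints <- function(candidates, trace, vel, params,
                              fixation = NULL, kind = "microsaccade") {
  rate <- trace$rate_hz
  ms_per_sample <- 1000 / rate
  out <- empty_events()
  if (nrow(candidates) == 0) {
    return(out)
  }
  cand <- candidates[order(candidates$onset), , drop = FALSE]

  if (!is.null(fixation)) {
    ign_s <- floor(params$ignore_fix_start_ms / ms_per_sample + 1e-9)
    ign_e <- floor(params$ignore_fix_end_ms / ms_per_sample + 1e-9)
    lo <- fixation$onset + ign_s     # first admissible sample
    hi <- fixation$offset - ign_e    # first inadmissible sample at the end
    keep <- cand$onset >= lo & cand$offset <= hi
    cand <- cand[keep, , drop = FALSE]
  }

  if (params$ignore_around_missing_ms > 0 && nrow(cand)) {
    gaps <- missing_ranges(trace)
    if (nrow(gaps)) {
      pad <- floor(params$ignore_around_missing_ms / ms_per_sample + 1e-9)
      near <- vapply(seq_len(nrow(cand)), function(i) {
        any(cand$onset[i] < gaps$offset + pad &
              cand$offset[i] > gaps$onset - pad)
      }, logical(1))
      cand <- cand[!near, , drop = FALSE]
    }
  }
  if (nrow(cand) == 0) {
    return(out)
  }

  rows <- lapply(seq_len(nrow(cand)), function(i) {
    on <- cand$onset[i]
    off <- cand$offset[i]
    k <- event_kinematics(trace, vel, on, off)
    data.frame(
      kind = kind, eye = trace$eye,
      onset = on, offset = off,
      onset_t = trace$t0 + (on - 1) / rate,
      offset_t = trace$t0 + (off - 1) / rate,
      duration_ms = (off - on) * ms_per_sample,
      dx = k$dx, dy = k$dy, amp_x = k$amp_x, amp_y = k$amp_y,
      amplitude = k$amplitude, peak_velocity = k$peak_velocity,
      direction_deg = k$direction_deg,
      fixation_id = if (is.null(fixation)) NA_integer_ else fixation$fixation_id,
      t_in_fixation_ms = if (is.null(fixation)) NA_real_ else
        (on - fixation$onset) * ms_per_sample,
      onset_left = NA_integer_, offset_left = NA_integer_,
      onset_right = NA_integer_, offset_right = NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  ev <- do.call(rbind, rows)

  ok <- ev$duration_ms >= params$min_dur_ms - 1e-9 &
    ev$duration_ms <= params$max_dur_ms + 1e-9 &
    ev$amplitude >= params$min_amp_deg &
    ev$amplitude <= params$max_amp_deg &
    !is.na(ev$peak_velocity) &
    ev$peak_velocity >= params$min_pv_degs &
    ev$peak_velocity <= params$max_pv_degs
  ev <- ev[ok, , drop = FALSE]
  if (nrow(ev) == 0) {
    return(out)
  }

  keep <- logical(nrow(ev))
  last_off_t <- -Inf
  for (i in seq_len(nrow(ev))) {
    gap_ms <- (ev$onset_t[i] - last_off_t) * 1000
    if (gap_ms >= params$min_isi_ms - 1e-9) {
      keep[i] <- TRUE
      last_off_t <- ev$offset_t[i]
    }
  }
  ev <- ev[keep, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Merge monocular events into binocular events
#'
#' A binocular event is a pair of left/right events with temporal
#' overlap of at least one sample.  Pairs are chosen greedily by
#' largest overlap (ties: earlier right event); each monocular event
#' joins at most one pair.  The merged interval is the union of the
#' pair; headline kinematics are the mean of the two eyes (direction:
#' circular mean); the per-eye intervals are kept in `onset_left` /
#' `offset_left` / `onset_right` / `offset_right`.
#'
#' @param left_events,right_events Event data frames of the two eyes
#'   (sorted, pairwise disjoint within each eye).
#' @param rate_hz Sampling rate, needed to recompute times/durations of
#'   the union intervals.
#' @param t0 Trial start time in seconds.
#' @return Event data frame with `eye = "binocular"`.
#' @export
merge_binocular <- function(left_events, right_events, rate_hz, t0 = 0) {
  L <- left_events
  R <- right_events
  out <- empty_events()
  if (nrow(L) == 0 || nrow(R) == 0) {
    return(out)
  }
  pairs <- expand.grid(i = seq_len(nrow(L)), j = seq_len(nrow(R)))
  ov <- pmin(L$offset[pairs$i], R$offset[pairs$j]) -
    pmax(L$onset[pairs$i], R$onset[pairs$j])
  pairs <- pairs[ov >= 1L, , drop = FALSE]
  ov <- ov[ov >= 1L]
  if (nrow(pairs) == 0) {
    return(out)
  }
  ord <- order(-ov, R$onset[pairs$j], L$onset[pairs$i])
  pairs <- pairs[ord, , drop = FALSE]
  used_l <- logical(nrow(L))
  used_r <- logical(nrow(R))
  picked <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]
    j <- pairs$j[k]
    if (used_l[i] || used_r[j]) next
    used_l[i] <- TRUE
    used_r[j] <- TRUE
    picked[[length(picked) + 1L]] <- c(i, j)
  }
  ms_per_sample <- 1000 / rate_hz
  rows <- lapply(picked, function(p) {
    l <- L[p[1], ]
    r <- R[p[2], ]
    on <- min(l$onset, r$onset)
    off <- max(l$offset, r$offset)
    dirs <- c(l$direction_deg, r$direction_deg) * pi / 180
    mdir <- (atan2(mean(sin(dirs)), mean(cos(dirs))) * 180 / pi) %% 360
    fix_id <- l$fixation_id
    data.frame(
      kind = l$kind, eye = "binocular",
      onset = on, offset = off,
      onset_t = t0 + (on - 1) / rate_hz,
      offset_t = t0 + (off - 1) / rate_hz,
      duration_ms = (off - on) * ms_per_sample,
      dx = (l$dx + r$dx) / 2, dy = (l$dy + r$dy) / 2,
      amp_x = (l$amp_x + r$amp_x) / 2, amp_y = (l$amp_y + r$amp_y) / 2,
      amplitude = (l$amplitude + r$amplitude) / 2,
      peak_velocity = (l$peak_velocity + r$peak_velocity) / 2,
      direction_deg = mdir,
      fixation_id = fix_id,
      t_in_fixation_ms = if (is.na(fix_id)) NA_real_ else
        l$t_in_fixation_ms - (l$onset - on) * ms_per_sample,
      onset_left = l$onset, offset_left = l$offset,
      onset_right = r$onset, offset_right = r$offset,
      stringsAsFactors = FALSE
    )
  })
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Detect saccades in a whole-trial trace
#'
#' Runs the velocity-threshold pipeline over the full trace: velocity
#' estimation, robust dispersion over all defined samples, elliptic
#' thresholding, then the duration/amplitude/peak-velocity bounds and
#' minimum inter-saccadic interval of `params`.
#'
#' @param trace A [gaze_trace()] in degrees.
#' @param params A [saccade_params()].
#' @return Event data frame with `kind = "saccade"`.
#' @export
detect_saccades <- function(trace, params = saccade_params()) {
  if (trace$unit != "deg") {
    stop("trace must be in visual degrees (see pixels_to_degrees)",
         call. = FALSE)
  }
  vel <- estimate_velocity(trace, params$vel_window)
  sigma <- robust_sigma(vel)
  min_dur_samples <- max(1L, as.integer(ceiling(
    params$min_dur_ms * trace$rate_hz / 1000 - 1e-9)))
  cand <- threshold_candidates(vel, sigma, params$lambda, min_dur_samples)
  apply_constraints(cand, trace, vel, params, fixation = NULL,
                    kind = "saccade")
}

#' Derive fixations as the intervals between saccades
#'
#' Fixations are the complement of the saccade intervals over the trace
#' span (including trace start to first saccade and last saccade to
#' trace end), with missing-data ranges subtracted.  Fixations shorter
#' than one velocity window are dropped.  Centroids are means of the
#' valid samples in the span.
#'
#' @param trace A [gaze_trace()].
#' @param saccades Saccade event data frame (sorted, disjoint).
#' @param min_samples Minimum fixation length in samples (default: the
#'   microsaccade filter's velocity window).
#' @return Data frame with `fixation_id`, `onset`, `offset` (1-based,
#'   half-open), `onset_t`, `offset_t`, `duration_ms`, `cx`, `cy`.
#' @export
derive_fixations <- function(trace, saccades, min_samples = 5L) {
  n <- length(trace$x)
  occupied <- rep(FALSE, n)
  if (!is.null(saccades) && nrow(saccades)) {
    for (i in seq_len(nrow(saccades))) {
      occupied[saccades$onset[i]:(saccades$offset[i] - 1L)] <- TRUE
    }
  }
  occupied[!trace$valid] <- TRUE
  runs <- index_runs(which(!occupied))
  runs <- runs[(runs$offset - runs$onset) >= min_samples, , drop = FALSE]
  fixation_table(trace, runs$onset, runs$offset)
}

# build the fixation table (ids, times, centroids) from interval bounds
fixation_table <- function(trace, onset, offset) {
  rate <- trace$rate_hz
  n <- length(onset)
  cx <- numeric(n)
  cy <- numeric(n)
  for (i in seq_len(n)) {
    span <- onset[i]:(offset[i] - 1L)
    ok <- span[trace$valid[span]]
    cx[i] <- if (length(ok)) mean(trace$x[ok]) else NA_real_
    cy[i] <- if (length(ok)) mean(trace$y[ok]) else NA_real_
  }
  data.frame(
    fixation_id = seq_len(n),
    onset = as.integer(onset), offset = as.integer(offset),
    onset_t = trace$t0 + (onset - 1) / rate,
    offset_t = trace$t0 + (offset - 1) / rate,
    duration_ms = (offset - onset) * 1000 / rate,
    cx = cx, cy = cy
  )
}

#' Detect fixations of a trial with the saccade filter
#'
#' Convenience wrapper: runs [detect_saccades()] on the trace selected
#' by `eye` (default: the averaged trace when both eyes are present,
#' otherwise the single available eye) and derives fixations from it.
#'
#' @param trial A [gaze_trial()].
#' @param params A [saccade_params()].
#' @param eye Eye used for fixation derivation, or `NULL` for the
#'   default above.
#' @param min_samples Passed to [derive_fixations()].
#' @return Fixation data frame.
#' @export
detect_fixations <- function(trial, params = saccade_params(), eye = NULL,
                             min_samples = 5L) {
  if (is.null(eye)) {
    eyes <- names(trial$traces)
    eye <- if (all(c("left", "right") %in% eyes) || "averaged" %in% eyes) {
      "averaged"
    } else {
      eyes[[1]]
    }
  }
  trace <- trial_trace(trial, eye)
  sac <- detect_saccades(trace, params)
  derive_fixations(trace, sac, min_samples = min_samples)
}

# union of fixation interior sample indices
fixation_scope_idx <- function(fixations) {
  if (nrow(fixations) == 0) return(integer(0))
  unlist(lapply(seq_len(nrow(fixations)), function(i) {
    fixations$onset[i]:(fixations$offset[i] - 1L)
  }))
}

# monocular detection over all fixations of one trace
detect_ms_one_eye <- function(trace, fixations, params) {
  vel <- estimate_velocity(trace, params$vel_window)
  min_dur_samples <- max(1L, as.integer(ceiling(
    params$min_dur_ms * trace$rate_hz / 1000 - 1e-9)))
  pooled_sigma <- NULL
  if (params$sigma_scope == "trial") {
    pooled_sigma <- robust_sigma(vel, fixation_scope_idx(fixations))
  }
  res <- list()
  for (i in seq_len(nrow(fixations))) {
    fix <- fixations[i, ]
    scope <- fix$onset:(fix$offset - 1L)
    sigma <- pooled_sigma
    if (is.null(sigma)) {
      sigma <- tryCatch(robust_sigma(vel, scope), error = function(e) NULL)
      if (is.null(sigma)) next  # too little signal in this fixation
    }
    cand <- threshold_candidates(vel, sigma, params$lambda,
                                 min_dur_samples, scope = scope)
    res[[length(res) + 1L]] <-
      apply_constraints(cand, trace, vel, params, fixation = fix,
                        kind = "microsaccade")
  }
  if (length(res) == 0) return(empty_events())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Detect microsaccades within fixations
#'
#' The full microsaccade pipeline: per eye mode, estimates velocity,
#' the robust dispersion (pooled over all fixation samples of the trial
#' or per fixation, see `sigma_scope`), finds super-threshold runs
#' within each fixation, and applies the extended constraints.  In
#' binocular mode both eyes are processed and only temporally
#' overlapping pairs are kept (see [merge_binocular()]).
#'
#' @param trial A [gaze_trial()] with traces in degrees.
#' @param fixations Fixation data frame (e.g. from [detect_fixations()]
#'   or precomputed ones imported with the trial).  If `NULL`, the
#'   trial's stored fixations are used, or fixations are derived with
#'   default saccade-filter settings.
#' @param params A [microsaccade_params()].
#' @return Event data frame; one row per microsaccade, carrying
#'   interval, kinematics (displacement, signed coordinate ranges,
#'   amplitude, peak velocity, direction), the owning fixation id and
#'   the onset time within that fixation.
#' @export
detect_microsaccades <- function(trial, fixations = NULL,
                                 params = microsaccade_params()) {
  if (is.null(fixations)) {
    fixations <- trial_fixations(trial)
  }
  mode <- params$eye_mode
  if (mode %in% c("left", "right", "averaged")) {
    trace <- trial_trace(trial, mode)
    return(detect_ms_one_eye(trace, fixations, params))
  }
  # binocular
  if (is.null(trial$traces$left) || is.null(trial$traces$right)) {
    stop("binocular detection requires both left and right eye traces",
         call. = FALSE)
  }
  lev <- detect_ms_one_eye(trial$traces$left, fixations, params)
  rev_ <- detect_ms_one_eye(trial$traces$right, fixations, params)
  res <- list()
  for (id in fixations$fixation_id) {
    l <- lev[!is.na(lev$fixation_id) & lev$fixation_id == id, , drop = FALSE]
    r <- rev_[!is.na(rev_$fixation_id) & rev_$fixation_id == id, , drop = FALSE]
    if (nrow(l) == 0 || nrow(r) == 0) next
    res[[length(res) + 1L]] <-
      merge_binocular(l, r, trial$traces$left$rate_hz, trial$traces$left$t0)
  }
  if (length(res) == 0) return(empty_events())
  out <- do.call(rbind, res)
  out <- out[order(out$onset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# fixations of a trial: stored ones (completed with centroids) or
# freshly derived with default saccade-filter settings
trial_fixations <- function(trial, sacc_params = saccade_params(),
                            eye = NULL) {
  fx <- trial$fixations
  if (!is.null(fx) && nrow(fx)) {
    if (is.null(eye)) {
      eyes <- names(trial$traces)
      eye <- if (all(c("left", "right") %in% eyes) || "averaged" %in% eyes) {
        "averaged"
      } else {
        eyes[[1]]
      }
    }
    trace <- trial_trace(trial, eye)
    return(fixation_table(trace, fx$onset, fx$offset))
  }
  detect_fixations(trial, sacc_params, eye = eye)
}
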
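#' Configuration for the synthetic gaze simulator
#'
#' Defaults emulate a 500 Hz binocular recording of relatively long,
#' stable fixations: fixational drift as a 2D random walk, large
#' saccades between fixation targets, injected microsaccades with a
#' raised-cosine velocity profile obeying a main-sequence law
#' `peak_velocity = gain * amplitude^exponent`, optional post-saccadic
#' glissades (overshoot-and-return right after saccade offset),
#' sensor dropouts, and per-eye independent noise on top of a shared
#' binocular signal.
#'
#' @param rate_hz Sampling rate (>= 200).
#' @param trial_s Trial duration in seconds.
#' @param fix_dur_range_s Uniform range of fixation durations.
#' @param sacc_amp_range_deg,sacc_dur_range_ms Saccade amplitude and
#'   duration ranges.
#' @param drift_sd_deg Random-walk step SD per sample (fixational
#'   drift).
#' @param noise_sd_deg Per-eye, per-sample sensor noise SD.
#' @param ms_rate_per_s Mean microsaccade rate per second of usable
#'   fixation time.
#' @param ms_amp_range_deg,ms_dur_range_ms Microsaccade amplitude and
#'   duration ranges (durations are clipped to this range after the
#'   main-sequence law fixes the peak velocity).
#' @param ms_gain,ms_exponent Main-sequence law parameters:
#'   `peak_velocity = ms_gain * amplitude^ms_exponent` (deg/s).
#' @param ms_margin_start_ms,ms_margin_end_ms Injected microsaccades
#'   keep this distance from fixation onset/offset (microsaccades do
#'   not occur during the post-saccadic settling period).
#' @param ms_min_gap_ms Minimum gap between injected microsaccades
#'   within a fixation (refractory period).
#' @param glissade_prob Probability that a saccade is followed by a
#'   glissade.
#' @param glissade_overshoot Overshoot fraction of the saccade
#'   amplitude.
#' @param glissade_dur_range_ms Glissade duration range.
#' @param dropout_rate_per_s,dropout_dur_range_ms Rate and length of
#'   missing-data gaps.
#' @param binocular Generate left and right eyes (`TRUE`) or a single
#'   right eye (`FALSE`).
#' @param field_deg Positions are kept within +/- this visual angle.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(rate_hz = 500, trial_s = 15,
                       fix_dur_range_s = c(0.8, 2.0),
                       sacc_amp_range_deg = c(3, 8),
                       sacc_dur_range_ms = c(30, 50),
                       drift_sd_deg = 0.001,
                       noise_sd_deg = 0.01,
                       ms_rate_per_s = 1.5,
                       ms_amp_range_deg = c(0.1, 0.8),
                       ms_dur_range_ms = c(6, 30),
                       ms_gain = 60, ms_exponent = 1,
                       ms_margin_start_ms = 60,
                       ms_margin_end_ms = 40,
                       ms_min_gap_ms = 120,
                       glissade_prob = 0.5,
                       glissade_overshoot = 0.1,
                       glissade_dur_range_ms = c(15, 35),
                       dropout_rate_per_s = 0.02,
                       dropout_dur_range_ms = c(40, 150),
                       binocular = TRUE,
                       field_deg = 10) {
  cfg <- list(rate_hz = rate_hz, trial_s = trial_s,
              fix_dur_range_s = fix_dur_range_s,
              sacc_amp_range_deg = sacc_amp_range_deg,
              sacc_dur_range_ms = sacc_dur_range_ms,
              drift_sd_deg = drift_sd_deg, noise_sd_deg = noise_sd_deg,
              ms_rate_per_s = ms_rate_per_s,
              ms_amp_range_deg = ms_amp_range_deg,
              ms_dur_range_ms = ms_dur_range_ms,
              ms_gain = ms_gain, ms_exponent = ms_exponent,
              ms_margin_start_ms = ms_margin_start_ms,
              ms_margin_end_ms = ms_margin_end_ms,
              ms_min_gap_ms = ms_min_gap_ms,
              glissade_prob = glissade_prob,
              glissade_overshoot = glissade_overshoot,
              glissade_dur_range_ms = glissade_dur_range_ms,
              dropout_rate_per_s = dropout_rate_per_s,
              dropout_dur_range_ms = dropout_dur_range_ms,
              binocular = isTRUE(binocular), field_deg = field_deg)
  if (rate_hz < 200) {
    stop("simulator requires rate_hz >= 200", call. = FALSE)
  }
  rng <- c("fix_dur_range_s", "sacc_amp_range_deg", "sacc_dur_range_ms",
           "ms_amp_range_deg", "ms_dur_range_ms", "glissade_dur_range_ms",
           "dropout_dur_range_ms")
  for (f in rng) {
    v <- cfg[[f]]
    if (length(v) != 2 || any(v <= 0) || v[1] > v[2]) {
      stop(f, " must be a positive increasing range", call. = FALSE)
    }
  }
  if (round(rate_hz * trial_s) < 2 * round(cfg$fix_dur_range_s[1] * rate_hz)) {
    stop("trial too short for the configured fixation durations",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# independent RNG substream per phenomenon: toggling one feature leaves
# the draws of all others bit-identical
sim_substream <- function(seed, phase) {
  s <- (as.numeric(seed) %% 1e6) * 1009 + phase * 7919 + 17
  set.seed(as.integer(s %% 2147483647))
}

# raised-cosine displacement profile: fraction of total displacement
# reached after tau in (0, 1]; velocity is vp/2 * (1 - cos(2*pi*tau))
# with vp = 2 * amplitude / duration
raised_cosine_frac <- function(tau) {
  tau - sin(2 * pi * tau) / (2 * pi)
}

# add one movement's displacement profile to coordinate series
add_profile <- function(x, onset, offset, total) {
  n <- length(x)
  len <- offset - onset
  j <- onset:(offset - 1L)
  x[j] <- x[j] + total * raised_cosine_frac(seq_len(len) / len)
  if (offset <= n) {
    x[offset:n] <- x[offset:n] + total
  }
  x
}

#' Simulate one labeled gaze trial
#'
#' Reproducible given `(config, seed)`.  Each phenomenon (scanpath
#' layout, microsaccades, glissades, drift, dropouts, noise) draws from
#' its own RNG substream, so disabling one leaves the others
#' bit-identical.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param trial_id,participant_id,condition Identifiers stored on the
#'   trial.
#' @return List with `trial` (a [gaze_trial()], traces in degrees) and
#'   `truth`: data frames of true fixation, saccade, microsaccade
#'   (with amplitude, direction, duration, peak velocity), glissade and
#'   gap intervals (1-based half-open sample indices).
#' @export
simulate_trial <- function(config = sim_config(), seed = 1L,
                           trial_id = "t1", participant_id = "p1",
                           condition = NA_character_) {
  rate <- config$rate_hz
  n <- as.integer(round(rate * config$trial_s))
  spp <- function(ms) as.integer(round(ms * rate / 1000))

  ## phase 1: scanpath layout (fixation/saccade alternation + targets)
  sim_substream(seed, 1L)
  fix_on <- integer(0); fix_off <- integer(0)
  sac_on <- integer(0); sac_off <- integer(0)
  sac_amp <- numeric(0); sac_dir <- numeric(0); sac_len <- integer(0)
  pos <- c(stats::runif(1, -2, 2), stats::runif(1, -2, 2))
  pos0 <- pos
  targets <- list()
  cursor <- 1L
  repeat {
    flen <- spp(1000 * stats::runif(1, config$fix_dur_range_s[1],
                                    config$fix_dur_range_s[2]))
    fend <- min(cursor + flen, n + 1L)
    fix_on <- c(fix_on, cursor)
    fix_off <- c(fix_off, fend)
    cursor <- fend
    if (cursor > n) break
    slen <- spp(stats::runif(1, config$sacc_dur_range_ms[1],
                             config$sacc_dur_range_ms[2]))
    if (cursor + slen > n + 1L) {  # not enough room for another saccade
      fix_off[length(fix_off)] <- n + 1L
      break
    }
    A <- stats::runif(1, config$sacc_amp_range_deg[1],
                      config$sacc_amp_range_deg[2])
    theta <- stats::runif(1, 0, 2 * pi)
    for (try in 1:20) {
      cand <- pos + A * c(cos(theta), -sin(theta))
      if (all(abs(cand) <= config$field_deg)) break
      theta <- if (try < 20) stats::runif(1, 0, 2 * pi) else
        atan2(-pos[2], -pos[1])
      cand <- pos + A * c(cos(theta), -sin(theta))
    }
    sac_on <- c(sac_on, cursor)
    sac_off <- c(sac_off, cursor + slen)
    sac_amp <- c(sac_amp, A)
    sac_dir <- c(sac_dir, theta)
    sac_len <- c(sac_len, slen)
    pos <- cand
    targets[[length(targets) + 1L]] <- pos
    cursor <- cursor + slen
  }
  fix_off[length(fix_off)] <- min(fix_off[length(fix_off)], n + 1L)

  ## phase 2: microsaccade injection within fixations
  sim_substream(seed, 2L)
  margin_s <- spp(config$ms_margin_start_ms)
  margin_e <- spp(config$ms_margin_end_ms)
  gap_spl <- spp(config$ms_min_gap_ms)
  ms <- list()
  for (i in seq_along(fix_on)) {
    lo <- fix_on[i] + margin_s
    hi <- fix_off[i] - margin_e
    if (hi - lo < spp(config$ms_dur_range_ms[2]) + 1L) next
    usable_s <- (hi - lo) / rate
    k <- stats::rpois(1, config$ms_rate_per_s * usable_s)
    if (k == 0) next
    onsets <- sort(as.integer(stats::runif(k, lo, hi)))
    amps <- stats::runif(k, config$ms_amp_range_deg[1],
                         config$ms_amp_range_deg[2])
    dirs <- stats::runif(k, 0, 360)
    prev_end <- -Inf
    for (j in seq_len(k)) {
      A <- amps[j]
      vp <- config$ms_gain * A^config$ms_exponent
      dur_ms <- min(max(2 * A / vp * 1000, config$ms_dur_range_ms[1]),
                    config$ms_dur_range_ms[2])
      len <- max(2L, spp(dur_ms))
      on <- onsets[j]
      off <- on + len
      if (on < prev_end + gap_spl || off > hi) next
      prev_end <- off
      ms[[length(ms) + 1L]] <- data.frame(
        onset = on, offset = off, amplitude = A, direction_deg = dirs[j],
        duration_ms = len * 1000 / rate,
        peak_velocity = 2 * A / (len / rate))
    }
  }
  truth_ms <- if (length(ms)) do.call(rbind, ms) else
    data.frame(onset = integer(0), offset = integer(0),
               amplitude = numeric(0), direction_deg = numeric(0),
               duration_ms = numeric(0), peak_velocity = numeric(0))

  ## phase 3: glissades (overshoot-and-return after saccade offset)
  sim_substream(seed, 3L)
  gl <- list()
  gl_flag <- if (length(sac_on)) stats::runif(length(sac_on)) < config$glissade_prob else logical(0)
  gl_len <- if (length(sac_on)) spp(stats::runif(length(sac_on),
                                                 config$glissade_dur_range_ms[1],
                                                 config$glissade_dur_range_ms[2])) else integer(0)
  for (i in seq_along(sac_on)) {
    if (!gl_flag[i]) next
    on <- sac_off[i]
    off <- on + gl_len[i]
    if (off > n + 1L) next
    gl[[length(gl) + 1L]] <- data.frame(
      onset = on, offset = off,
      amplitude = config$glissade_overshoot * sac_amp[i],
      direction_deg = (sac_dir[i] * 180 / pi + 180) %% 360)
  }
  truth_gl <- if (length(gl)) do.call(rbind, gl) else
    data.frame(onset = integer(0), offset = integer(0),
               amplitude = numeric(0), direction_deg = numeric(0))

  ## deterministic trace assembly from the event lists
  x <- rep(pos0[1], n)
  y <- rep(pos0[2], n)
  gl_used <- 0L
  for (i in seq_along(sac_on)) {
    has_gl <- gl_flag[i] && (sac_off[i] + gl_len[i] <= n + 1L)
    f <- if (has_gl) 1 + config$glissade_overshoot else 1
    dx <- f * sac_amp[i] * cos(sac_dir[i])
    dy <- -f * sac_amp[i] * sin(sac_dir[i])
    x <- add_profile(x, sac_on[i], sac_off[i], dx)
    y <- add_profile(y, sac_on[i], sac_off[i], dy)
    if (has_gl) {
      gl_used <- gl_used + 1L
      bx <- -config$glissade_overshoot * sac_amp[i] * cos(sac_dir[i])
      by <- config$glissade_overshoot * sac_amp[i] * sin(sac_dir[i])
      x <- add_profile(x, sac_off[i], sac_off[i] + gl_len[i], bx)
      y <- add_profile(y, sac_off[i], sac_off[i] + gl_len[i], by)
    }
  }
  if (nrow(truth_ms)) {
    for (i in seq_len(nrow(truth_ms))) {
      th <- truth_ms$direction_deg[i] * pi / 180
      x <- add_profile(x, truth_ms$onset[i], truth_ms$offset[i],
                       truth_ms$amplitude[i] * cos(th))
      y <- add_profile(y, truth_ms$onset[i], truth_ms$offset[i],
                       -truth_ms$amplitude[i] * sin(th))
    }
  }

  ## phase 4: fixational drift (shared random walk)
  sim_substream(seed, 4L)
  if (config$drift_sd_deg > 0) {
    x <- x + cumsum(stats::rnorm(n, 0, config$drift_sd_deg))
    y <- y + cumsum(stats::rnorm(n, 0, config$drift_sd_deg))
  }

  ## phase 5: dropouts
  sim_substream(seed, 5L)
  valid <- rep(TRUE, n)
  kdrop <- stats::rpois(1, config$dropout_rate_per_s * config$trial_s)
  if (kdrop > 0) {
    d_on <- as.integer(stats::runif(kdrop, 1, n))
    d_len <- spp(stats::runif(kdrop, config$dropout_dur_range_ms[1],
                              config$dropout_dur_range_ms[2]))
    for (i in seq_len(kdrop)) {
      valid[d_on[i]:min(d_on[i] + d_len[i] - 1L, n)] <- FALSE
    }
  }
  truth_gaps <- index_runs(which(!valid))

  ## phase 6: per-eye sensor noise on top of the shared signal
  sim_substream(seed, 6L)
  noise <- function() stats::rnorm(n, 0, config$noise_sd_deg)
  lx <- x + noise(); ly <- y + noise()
  rx <- x + noise(); ry <- y + noise()
  traces <- if (config$binocular) {
    list(left = gaze_trace(lx, ly, rate, unit = "deg", eye = "left",
                           valid = valid),
         right = gaze_trace(rx, ry, rate, unit = "deg", eye = "right",
                            valid = valid))
  } else {
    list(right = gaze_trace(rx, ry, rate, unit = "deg", eye = "right",
                            valid = valid))
  }

  trial <- gaze_trial(trial_id, traces, participant_id = participant_id,
                      condition = condition)
  truth <- list(
    fixations = data.frame(onset = fix_on, offset = fix_off),
    saccades = data.frame(onset = sac_on, offset = sac_off,
                          amplitude = sac_amp,
                          direction_deg = (sac_dir * 180 / pi) %% 360),
    microsaccades = truth_ms,
    glissades = truth_gl,
    gaps = truth_gaps
  )
  list(trial = trial, truth = truth)
}

#' Simulate a participant (several trials)
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed; each trial uses its own substream.
#' @param participant_id Identifier.
#' @param n_trials Number of trials.
#' @param conditions Optional vector of condition labels cycled across
#'   trials.
#' @return List with `trials` (list of [gaze_trial()]) and `truths`
#'   (parallel list of ground-truth tables).
#' @export
simulate_participant <- function(config = sim_config(), seed = 1L,
                                 participant_id = "p1", n_trials = 3L,
                                 conditions = NULL) {
  trials <- vector("list", n_trials)
  truths <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    cond <- if (is.null(conditions)) NA_character_ else
      conditions[((i - 1L) %% length(conditions)) + 1L]
    r <- simulate_trial(config,
                        seed = (as.numeric(seed) * 131 + i * 7001) %% 2147483647,
                        trial_id = sprintf("%s_t%02d", participant_id, i),
                        participant_id = participant_id, condition = cond)
    trials[[i]] <- r$trial
    truths[[i]] <- r$truth
  }
  list(trials = trials, truths = truths)
}

#' Match detected events against ground truth
#'
#' Greedy one-to-one matching by interval overlap: candidate pairs must
#' overlap by at least one sample and agree on onset within `tol_ms`;
#' pairs are taken largest-overlap first.  Precision is
#' matched/detected (`NA` when nothing was detected), recall is
#' matched/truth.
#'
#' @param detected,truth Data frames with `onset`, `offset` (1-based
#'   half-open sample indices), sorted by onset.
#' @param rate_hz Sampling rate used to convert `tol_ms` to samples.
#' @param tol_ms Onset tolerance in milliseconds.
#' @return List with `precision`, `recall`, `n_detected`, `n_truth`,
#'   `matches` (data frame of index pairs).
#' @export
match_events <- function(detected, truth, rate_hz, tol_ms = 4) {
  nd <- nrow(detected)
  nt <- nrow(truth)
  matches <- data.frame(detected = integer(0), truth = integer(0))
  if (nd > 0 && nt > 0) {
    tol <- tol_ms * rate_hz / 1000 + 1e-9
    pairs <- expand.grid(i = seq_len(nd), j = seq_len(nt))
    ov <- pmin(detected$offset[pairs$i], truth$offset[pairs$j]) -
      pmax(detected$onset[pairs$i], truth$onset[pairs$j])
    dtol <- abs(detected$onset[pairs$i] - truth$onset[pairs$j]) <= tol
    sel <- ov >= 1L & dtol
    pairs <- pairs[sel, , drop = FALSE]
    ov <- ov[sel]
    ord <- order(-ov, pairs$j, pairs$i)
    pairs <- pairs[ord, , drop = FALSE]
    used_d <- logical(nd)
    used_t <- logical(nt)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (used_d[i] || used_t[j]) next
      used_d[i] <- TRUE; used_t[j] <- TRUE
      matches <- rbind(matches, data.frame(detected = i, truth = j))
    }
  }
  m <- nrow(matches)
  list(precision = if (nd > 0) m / nd else NA_real_,
       recall = if (nt > 0) m / nt else if (nd == 0) 1 else 0,
       n_detected = nd, n_truth = nt, matches = matches)
}
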
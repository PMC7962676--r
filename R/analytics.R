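#' Direction between two fixation centroids
#'
#' Direction of the vector from fixation `a`'s centroid to fixation
#' `b`'s centroid, in the package's screen-direction convention
#' (0 deg = rightward, 90 deg = up on screen, counter-clockwise).
#'
#' @param fix_a,fix_b One-row fixation data frames (or lists) with
#'   centroid fields `cx`, `cy` in screen coordinates (y down).
#' @return Angle in degrees in `[0, 360)`.
#' @export
inter_fixation_direction <- function(fix_a, fix_b) {
  dx <- fix_b$cx - fix_a$cx
  dy <- fix_b$cy - fix_a$cy
  if (dx == 0 && dy == 0) {
    stop("fixation centroids coincide; direction undefined", call. = FALSE)
  }
  screen_direction_deg(dx, dy)
}

#' Microsaccade directions relative to the next fixation
#'
#' Re-expresses each event's direction relative to the direction from
#' its owning fixation's centroid to the next fixation's centroid:
#' `rel = (direction - inter_fixation_direction) mod 360`, so 0 deg
#' means "toward the next fixation".  Events in the trial's last
#' fixation have no successor; they are excluded and counted in the
#' `n_excluded` attribute.
#'
#' @param events Event data frame with `direction_deg` and
#'   `fixation_id`.
#' @param fixations Fixation data frame of the same trial (sorted by
#'   onset, ids sequential).
#' @return Numeric vector of relative angles in degrees with attribute
#'   `n_excluded`.
#' @export
rotate_to_next_fixation <- function(events, fixations) {
  if (nrow(events) == 0) {
    return(structure(numeric(0), n_excluded = 0L))
  }
  last_id <- max(fixations$fixation_id)
  keep <- !is.na(events$fixation_id) & events$fixation_id < last_id
  ev <- events[keep, , drop = FALSE]
  rel <- vapply(seq_len(nrow(ev)), function(i) {
    id <- ev$fixation_id[i]
    fa <- fixations[fixations$fixation_id == id, ]
    fb <- fixations[fixations$fixation_id == id + 1L, ]
    (ev$direction_deg[i] - inter_fixation_direction(fa, fb)) %% 360
  }, numeric(1))
  structure(rel, n_excluded = sum(!keep))
}

#' Circular (rose-plot) histogram of directions
#'
#' Bins angles into `n_bins` half-open sectors `[k*360/n, (k+1)*360/n)`
#' and computes the circular mean direction `atan2(sum sin, sum cos)`
#' and circular standard deviation `sqrt(-2 ln R)` (degrees), where `R`
#' is the mean resultant length.
#'
#' @param angles_deg Numeric vector of directions in degrees.
#' @param n_bins Number of sectors (default 12).
#' @param condition_labels Optional label per angle; adds per-condition
#'   count columns.
#' @return An object of class `rose_histogram`: list with `n_bins`,
#'   `bin_edges_deg`, `counts` (total), `counts_by_condition` (matrix
#'   or `NULL`), `mean_dir_deg`, `circ_sd_deg`, `resultant_length`,
#'   `n`.  Empty input gives zero counts and `NA` mean/SD.
#' @export
rose_histogram <- function(angles_deg, n_bins = 12L,
                           condition_labels = NULL) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) {
    stop("n_bins must be >= 1", call. = FALSE)
  }
  a <- as.numeric(angles_deg) %% 360
  edges <- seq(0, 360, length.out = n_bins + 1L)
  bin <- pmin(floor(a / (360 / n_bins)), n_bins - 1L) + 1L
  counts <- tabulate(bin, nbins = n_bins)
  by_cond <- NULL
  if (!is.null(condition_labels)) {
    if (length(condition_labels) != length(a)) {
      stop("condition_labels must match angles in length", call. = FALSE)
    }
    by_cond <- table(factor(bin, levels = seq_len(n_bins)),
                     condition_labels)
    by_cond <- unclass(as.matrix(by_cond))
  }
  if (length(a) == 0) {
    mean_dir <- NA_real_
    csd <- NA_real_
    R <- NA_real_
  } else {
    rad <- a * pi / 180
    S <- mean(sin(rad))
    C <- mean(cos(rad))
    R <- sqrt(S^2 + C^2)
    mean_dir <- (atan2(S, C) * 180 / pi) %% 360
    csd <- if (R > 0) sqrt(-2 * log(R)) * 180 / pi else Inf
  }
  structure(
    list(n_bins = n_bins, bin_edges_deg = edges, counts = counts,
         counts_by_condition = by_cond, mean_dir_deg = mean_dir,
         circ_sd_deg = csd, resultant_length = R, n = length(a)),
    class = "rose_histogram"
  )
}

#' @export
print.rose_histogram <- function(x, ...) {
  cat(sprintf("<rose_histogram> %d angles in %d bins; mean direction %.1f deg, circular SD %.1f deg\n",
              x$n, x$n_bins, x$mean_dir_deg, x$circ_sd_deg))
  invisible(x)
}

#' Temporal-position histogram of events within fixations
#'
#' Counts event onsets per `[k*bin, (k+1)*bin)` ms measured from the
#' onset of the owning fixation.  A strong excess in the first 40 ms
#' bin is the typical signature of post-saccadic glissades mislabelled
#' as microsaccades.
#'
#' @param events Event data frame with `t_in_fixation_ms`.
#' @param bin_ms Bin width in milliseconds (default 40).
#' @param max_ms Optional histogram span; defaults to the largest onset
#'   observed.
#' @return Data frame with `bin_start_ms`, `bin_end_ms`, `count`.
#' @export
temporal_histogram <- function(events, bin_ms = 40, max_ms = NULL) {
  t <- events$t_in_fixation_ms
  t <- t[!is.na(t)]
  if (is.null(max_ms)) {
    max_ms <- if (length(t)) max(t) else 0
  }
  nb <- max(1L, as.integer(floor(max_ms / bin_ms)) + 1L)
  bin <- floor(t / bin_ms) + 1L
  bin <- bin[bin <= nb]
  counts <- tabulate(bin, nbins = nb)
  data.frame(bin_start_ms = (seq_len(nb) - 1L) * bin_ms,
             bin_end_ms = seq_len(nb) * bin_ms,
             count = counts)
}

#' Main-sequence pairs
#'
#' Amplitude / peak-velocity pairs for log-log (main sequence)
#' scatterplots.  Events with non-positive amplitude or peak velocity
#' cannot be drawn on logarithmic axes; they are excluded and counted.
#'
#' @param events Event data frame.
#' @return Data frame with `amplitude`, `peak_velocity` (event order),
#'   with attribute `n_excluded`.
#' @export
main_sequence <- function(events) {
  ok <- !is.na(events$amplitude) & events$amplitude > 0 &
    !is.na(events$peak_velocity) & events$peak_velocity > 0
  out <- data.frame(amplitude = events$amplitude[ok],
                    peak_velocity = events$peak_velocity[ok])
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Gaze samples translated (and optionally rotated) per fixation
#'
#' Translates each fixation's samples so the fixation centroid is the
#' origin, letting fixations be overlaid.  With `rotate = TRUE`,
#' each fixation's samples are additionally rotated so the direction
#' toward the next fixation points up; the last fixation (no
#' successor) is then skipped.  Returned coordinates are y-up plot
#' coordinates.
#'
#' @param trace A [gaze_trace()].
#' @param fixations Fixation data frame.
#' @param events Optional microsaccade event data frame; samples inside
#'   a microsaccade are flagged.
#' @param rotate Rotate so the next-fixation direction maps to up.
#' @return Data frame with `fixation_id`, `idx`, `x`, `y`,
#'   `in_microsaccade`.
#' @export
positions_relative_to_fixation <- function(trace, fixations, events = NULL,
                                           rotate = FALSE) {
  ms_mask <- rep(FALSE, length(trace$x))
  if (!is.null(events) && nrow(events)) {
    for (i in seq_len(nrow(events))) {
      ms_mask[events$onset[i]:(events$offset[i] - 1L)] <- TRUE
    }
  }
  last_id <- if (nrow(fixations)) max(fixations$fixation_id) else 0L
  out <- list()
  for (i in seq_len(nrow(fixations))) {
    fix <- fixations[i, ]
    if (rotate && fix$fixation_id == last_id) next
    span <- fix$onset:(fix$offset - 1L)
    span <- span[trace$valid[span]]
    # plot coordinates: y-up
    px <- trace$x[span] - fix$cx
    py <- -(trace$y[span] - fix$cy)
    if (rotate) {
      nxt <- fixations[fixations$fixation_id == fix$fixation_id + 1L, ]
      dir <- inter_fixation_direction(fix, nxt)
      th <- (90 - dir) * pi / 180
      rx <- cos(th) * px - sin(th) * py
      ry <- sin(th) * px + cos(th) * py
      px <- rx
      py <- ry
    }
    out[[length(out) + 1L]] <- data.frame(
      fixation_id = fix$fixation_id, idx = span, x = px, y = py,
      in_microsaccade = ms_mask[span])
  }
  if (length(out) == 0) {
    return(data.frame(fixation_id = integer(0), idx = integer(0),
                      x = numeric(0), y = numeric(0),
                      in_microsaccade = logical(0)))
  }
  do.call(rbind, out)
}

mean_sd <- function(v) {
  if (length(v) == 0) {
    return(c(mean = NA_real_, sd = NA_real_))
  }
  c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_)
}

# summary row for one group of trial results
summarize_group <- function(results) {
  fx <- do.call(rbind, lapply(results, function(r) {
    f <- r$fixations
    f$.trial <- r$trial_id
    f
  }))
  ms <- do.call(rbind, lapply(results, function(r) {
    e <- r$microsaccades
    if (nrow(e)) e$.trial <- r$trial_id else e$.trial <- character(0)
    e
  }))
  fix_count <- if (is.null(fx)) 0L else nrow(fx)
  fix_time_s <- if (fix_count) sum(fx$duration_ms) / 1000 else 0
  ms_count <- if (is.null(ms)) 0L else nrow(ms)
  with_ms <- 0L
  if (ms_count && fix_count) {
    keys_ms <- paste(ms$.trial, ms$fixation_id)
    keys_fx <- paste(fx$.trial, fx$fixation_id)
    with_ms <- sum(keys_fx %in% keys_ms)
  }
  isi <- numeric(0)
  if (ms_count > 1) {
    for (r in results) {
      e <- r$microsaccades
      if (nrow(e) < 2) next
      for (id in unique(e$fixation_id)) {
        o <- sort(e$onset_t[e$fixation_id == id])
        if (length(o) > 1) isi <- c(isi, diff(o) * 1000)
      }
    }
  }
  fd <- mean_sd(if (fix_count) fx$duration_ms else numeric(0))
  md <- mean_sd(if (ms_count) ms$duration_ms else numeric(0))
  ma <- mean_sd(if (ms_count) ms$amplitude else numeric(0))
  mp <- mean_sd(if (ms_count) ms$peak_velocity else numeric(0))
  mi <- mean_sd(isi)
  data.frame(
    n_trials = length(results),
    fixation_count = fix_count,
    fixation_duration_mean_ms = fd[["mean"]],
    fixation_duration_sd_ms = fd[["sd"]],
    pct_fixations_with_ms = if (fix_count) 100 * with_ms / fix_count else NA_real_,
    ms_count = ms_count,
    ms_duration_mean_ms = md[["mean"]], ms_duration_sd_ms = md[["sd"]],
    ms_amplitude_mean_deg = ma[["mean"]], ms_amplitude_sd_deg = ma[["sd"]],
    ms_peak_velocity_mean_degs = mp[["mean"]],
    ms_peak_velocity_sd_degs = mp[["sd"]],
    ms_per_second = if (fix_time_s > 0) ms_count / fix_time_s else 0,
    ms_per_fixation = if (fix_count) ms_count / fix_count else 0,
    isi_mean_ms = mi[["mean"]], isi_sd_ms = mi[["sd"]]
  )
}

#' Multi-level summary statistics
#'
#' Aggregates detection results at fixation-rate level: fixation count
#' and duration, percentage of fixations containing microsaccades,
#' microsaccade count, duration, amplitude and peak velocity (mean and
#' SD), microsaccade rate per second of fixation time and per fixation,
#' and the inter-saccadic interval (gaps between consecutive
#' microsaccade onsets within a fixation).  Groups above trial level
#' pool raw events — a condition-level row equals recomputation from
#' the pooled event list, not a mean of per-trial means.
#'
#' @param results List of per-trial detection results as returned by
#'   [analyze_trial()]: each a list with `trial_id`, `participant_id`,
#'   `condition`, `fixations`, `microsaccades`.
#' @param level `"trial"`, `"participant"`, `"condition"`,
#'   `"participant_condition"` or `"overall"`.
#' @return Data frame, one row per group, with grouping key columns
#'   followed by the statistics.
#' @export
summary_statistics <- function(results,
                               level = c("trial", "participant", "condition",
                                         "participant_condition", "overall")) {
  level <- match.arg(level)
  if (length(results) == 0) {
    return(data.frame())
  }
  key <- switch(level,
    trial = vapply(results, function(r) r$trial_id, character(1)),
    participant = vapply(results, function(r) r$participant_id, character(1)),
    condition = vapply(results, function(r) r$condition, character(1)),
    participant_condition = vapply(results, function(r)
      paste(r$participant_id, r$condition, sep = "\r"), character(1)),
    overall = rep("all", length(results))
  )
  rows <- lapply(split(seq_along(results), key), function(ii) {
    grp <- results[ii]
    stats <- summarize_group(grp)
    head_cols <- switch(level,
      trial = data.frame(trial_id = grp[[1]]$trial_id,
                         participant_id = grp[[1]]$participant_id,
                         condition = grp[[1]]$condition),
      participant = data.frame(participant_id = grp[[1]]$participant_id),
      condition = data.frame(condition = grp[[1]]$condition),
      participant_condition = data.frame(
        participant_id = grp[[1]]$participant_id,
        condition = grp[[1]]$condition),
      overall = data.frame(group = "all")
    )
    cbind(head_cols, stats)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full per-trial pipeline
#'
#' Detects (or reuses) fixations, then detects microsaccades within
#' them, and returns a self-contained per-trial result for aggregation
#' and export.
#'
#' @param trial A [gaze_trial()] with traces in degrees.
#' @param params A [microsaccade_params()].
#' @param sacc_params A [saccade_params()] used when fixations must be
#'   derived.
#' @param fixations Optional precomputed fixation data frame; default:
#'   the trial's stored fixations, else freshly derived.
#' @param refit_fixations Ignore stored fixations and re-derive them
#'   with the saccade filter.
#' @return List with `trial_id`, `participant_id`, `condition`,
#'   `fixations`, `microsaccades`, `saccades` (when derived) and the
#'   parameter objects used.
#' @export
analyze_trial <- function(trial, params = microsaccade_params(),
                          sacc_params = saccade_params(),
                          fixations = NULL, refit_fixations = FALSE) {
  saccades <- NULL
  if (is.null(fixations)) {
    if (!refit_fixations && !is.null(trial$fixations) &&
        nrow(trial$fixations)) {
      fixations <- trial_fixations(trial)
    } else {
      eyes <- names(trial$traces)
      eye <- if (all(c("left", "right") %in% eyes) || "averaged" %in% eyes) {
        "averaged"
      } else {
        eyes[[1]]
      }
      trace <- trial_trace(trial, eye)
      saccades <- detect_saccades(trace, sacc_params)
      fixations <- derive_fixations(trace, saccades,
                                    min_samples = params$vel_window)
    }
  }
  ms <- detect_microsaccades(trial, fixations, params)
  list(trial_id = trial$trial_id, participant_id = trial$participant_id,
       condition = trial$condition, fixations = fixations,
       microsaccades = ms, saccades = saccades,
       params = params, sacc_params = sacc_params)
}
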
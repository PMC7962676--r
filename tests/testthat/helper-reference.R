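# Independent naive reference implementation of the detection pipeline:
# per-sample scans and explicit loops throughout, written from the
# definitions, for cross-checking the package's vectorized path.

ref_velocity <- function(x, y, valid, rate, window) {
  n <- length(x)
  m <- (window - 1) / 2
  dt <- 1 / rate
  vx <- rep(NA_real_, n)
  vy <- rep(NA_real_, n)
  defined <- rep(FALSE, n)
  wsum <- sum(1:m)
  for (i in seq_len(n)) {
    if (i - m < 1 || i + m > n) next
    ok <- TRUE
    for (k in (i - m):(i + m)) if (!valid[k]) ok <- FALSE
    if (!ok) next
    sx <- 0; sy <- 0
    for (k in 1:m) {
      sx <- sx + x[i + k] - x[i - k]
      sy <- sy + y[i + k] - y[i - k]
    }
    vx[i] <- sx / (2 * dt * wsum)
    vy[i] <- sy / (2 * dt * wsum)
    defined[i] <- TRUE
  }
  list(vx = vx, vy = vy, defined = defined)
}

ref_sigma <- function(vel, scope) {
  sel <- intersect(which(vel$defined), scope)
  vx <- vel$vx[sel]; vy <- vel$vy[sel]
  c(sqrt(max(median(vx^2) - median(vx)^2, 0)),
    sqrt(max(median(vy^2) - median(vy)^2, 0)))
}

# per-sample boolean scan -> list of half-open runs
ref_runs <- function(hit) {
  runs <- list()
  start <- NA
  for (i in seq_along(hit)) {
    if (hit[i] && is.na(start)) start <- i
    if (!hit[i] && !is.na(start)) {
      runs[[length(runs) + 1]] <- c(start, i)
      start <- NA
    }
  }
  if (!is.na(start)) runs[[length(runs) + 1]] <- c(start, length(hit) + 1)
  runs
}

ref_event_props <- function(x, y, vel, on, off) {
  xs <- x[on:(off - 1)]; ys <- y[on:(off - 1)]
  sx <- sign(which.max(xs) - which.min(xs)); if (sx == 0) sx <- 1
  sy <- sign(which.max(ys) - which.min(ys)); if (sy == 0) sy <- 1
  ax <- sx * (max(xs) - min(xs))
  ay <- sy * (max(ys) - min(ys))
  pv <- -Inf
  for (i in on:(off - 1)) {
    if (vel$defined[i]) {
      sp <- sqrt(vel$vx[i]^2 + vel$vy[i]^2)
      if (sp > pv) pv <- sp
    }
  }
  list(amplitude = sqrt(ax^2 + ay^2), pv = if (is.finite(pv)) pv else NA)
}

# one eye, one fixation: scan, constrain, return kept intervals
ref_events_in_fixation <- function(trace, vel, sigma, fix, params) {
  rate <- trace$rate_hz
  mps <- 1000 / rate
  lam <- params$lambda
  hit <- rep(FALSE, length(trace$x))
  for (i in fix$onset:(fix$offset - 1)) {
    if (!vel$defined[i]) next
    if ((vel$vx[i] / (lam * sigma[1]))^2 +
        (vel$vy[i] / (lam * sigma[2]))^2 > 1) hit[i] <- TRUE
  }
  min_len <- max(1, ceiling(params$min_dur_ms * rate / 1000 - 1e-9))
  runs <- Filter(function(r) r[2] - r[1] >= min_len, ref_runs(hit))
  ign_s <- floor(params$ignore_fix_start_ms / mps + 1e-9)
  ign_e <- floor(params$ignore_fix_end_ms / mps + 1e-9)
  runs <- Filter(function(r) r[1] >= fix$onset + ign_s &&
                   r[2] <= fix$offset - ign_e, runs)
  if (params$ignore_around_missing_ms > 0) {
    pad <- floor(params$ignore_around_missing_ms / mps + 1e-9)
    gaps <- ref_runs(!trace$valid)
    runs <- Filter(function(r) {
      for (g in gaps) {
        if (r[1] < g[2] + pad && r[2] > g[1] - pad) return(FALSE)
      }
      TRUE
    }, runs)
  }
  kept <- list()
  for (r in runs) {
    pr <- ref_event_props(trace$x, trace$y, vel, r[1], r[2])
    dur <- (r[2] - r[1]) * mps
    if (dur < params$min_dur_ms - 1e-9 || dur > params$max_dur_ms + 1e-9) next
    if (pr$amplitude < params$min_amp_deg ||
        pr$amplitude > params$max_amp_deg) next
    if (is.na(pr$pv) || pr$pv < params$min_pv_degs ||
        pr$pv > params$max_pv_degs) next
    kept[[length(kept) + 1]] <- r
  }
  # minimum inter-saccadic interval, left to right
  out <- list()
  last_off_t <- -Inf
  for (r in kept) {
    onset_t <- (r[1] - 1) / rate
    if ((onset_t - last_off_t) * 1000 >= params$min_isi_ms - 1e-9) {
      out[[length(out) + 1]] <- r
      last_off_t <- (r[2] - 1) / rate
    }
  }
  out
}

ref_detect_one_eye <- function(trace, fixations, params) {
  vel <- ref_velocity(trace$x, trace$y, trace$valid, trace$rate_hz,
                      params$vel_window)
  scope <- integer(0)
  for (i in seq_len(nrow(fixations))) {
    scope <- c(scope, fixations$onset[i]:(fixations$offset[i] - 1))
  }
  sigma <- ref_sigma(vel, scope)
  res <- list()
  for (i in seq_len(nrow(fixations))) {
    fix <- fixations[i, ]
    evs <- ref_events_in_fixation(trace, vel, sigma, fix, params)
    for (e in evs) res[[length(res) + 1]] <- c(e, fix$fixation_id)
  }
  res
}

# greedy max-overlap pairing of left/right interval lists, then union
ref_binocular <- function(lev, rev_) {
  pairs <- list()
  for (i in seq_along(lev)) {
    for (j in seq_along(rev_)) {
      ov <- min(lev[[i]][2], rev_[[j]][2]) - max(lev[[i]][1], rev_[[j]][1])
      if (ov >= 1) pairs[[length(pairs) + 1]] <- c(i, j, ov)
    }
  }
  if (length(pairs) == 0) return(list())
  pm <- do.call(rbind, pairs)
  r_on <- sapply(pm[, 2], function(j) rev_[[j]][1])
  l_on <- sapply(pm[, 1], function(i) lev[[i]][1])
  pm <- pm[order(-pm[, 3], r_on, l_on), , drop = FALSE]
  used_l <- rep(FALSE, length(lev))
  used_r <- rep(FALSE, length(rev_))
  out <- list()
  for (k in seq_len(nrow(pm))) {
    i <- pm[k, 1]; j <- pm[k, 2]
    if (used_l[i] || used_r[j]) next
    used_l[i] <- TRUE; used_r[j] <- TRUE
    out[[length(out) + 1]] <- c(min(lev[[i]][1], rev_[[j]][1]),
                                max(lev[[i]][2], rev_[[j]][2]))
  }
  out[order(sapply(out, `[`, 1))]
}

ref_detect_saccades <- function(trace, params) {
  vel <- ref_velocity(trace$x, trace$y, trace$valid, trace$rate_hz,
                      params$vel_window)
  sigma <- ref_sigma(vel, seq_along(trace$x))
  fix <- data.frame(onset = 1, offset = length(trace$x) + 1,
                    fixation_id = NA)
  p <- params
  p$ignore_fix_start_ms <- 0
  p$ignore_fix_end_ms <- 0
  ref_events_in_fixation(trace, vel, sigma, fix, p)
}

ref_derive_fixations <- function(trace, sacc_runs, min_samples) {
  n <- length(trace$x)
  free <- rep(TRUE, n)
  for (r in sacc_runs) free[r[1]:(r[2] - 1)] <- FALSE
  for (i in seq_len(n)) if (!trace$valid[i]) free[i] <- FALSE
  Filter(function(r) r[2] - r[1] >= min_samples, ref_runs(free))
}

# full naive pipeline on a binocular trial; returns interval matrices
ref_pipeline <- function(trial, ms_params, sc_params) {
  avg <- average_eyes(trial$traces$left, trial$traces$right)
  sacc <- ref_detect_saccades(avg, sc_params)
  fx_runs <- ref_derive_fixations(avg, sacc, ms_params$vel_window)
  fixations <- data.frame(
    fixation_id = seq_along(fx_runs),
    onset = sapply(fx_runs, `[`, 1),
    offset = sapply(fx_runs, `[`, 2))
  lev <- ref_detect_one_eye(trial$traces$left, fixations, ms_params)
  rev_ <- ref_detect_one_eye(trial$traces$right, fixations, ms_params)
  ms <- list()
  for (id in fixations$fixation_id) {
    l <- Filter(function(e) e[3] == id, lev)
    r <- Filter(function(e) e[3] == id, rev_)
    ms <- c(ms, ref_binocular(l, r))
  }
  to_mat <- function(lst, k = 2) {
    if (length(lst) == 0) return(matrix(numeric(0), ncol = k))
    do.call(rbind, lapply(lst, function(e) e[1:k]))
  }
  list(saccades = to_mat(sacc),
       fixations = cbind(fixations$onset, fixations$offset),
       microsaccades = to_mat(ms))
}
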
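test_that("threshold test is strict and respects minimum duration", {
  sigma <- c(sigma_x = 1, sigma_y = 1)
  lam <- 5
  # every sample exactly on the ellipse boundary -> no candidates
  v_eq <- fake_vel(rep(lam, 20), rep(0, 20))
  expect_identical(nrow(threshold_candidates(v_eq, sigma, lam)), 0L)

  # one 5-sample super-threshold run
  vx <- rep(0.1, 30)
  vx[10:14] <- 20
  cand <- threshold_candidates(fake_vel(vx, rep(0.1, 30)), sigma, lam,
                               min_dur_samples = 3L)
  expect_equal(cand$onset, 10L)
  expect_equal(cand$offset, 15L)
  # raising min duration above the run length removes it
  expect_identical(
    nrow(threshold_candidates(fake_vel(vx, rep(0.1, 30)), sigma, lam,
                              min_dur_samples = 6L)), 0L)
})

test_that("runs never bridge masked samples", {
  vx <- rep(20, 12)
  def <- rep(TRUE, 12)
  def[6] <- FALSE
  cand <- threshold_candidates(fake_vel(vx, vx, defined = def),
                               c(1, 1), 5, min_dur_samples = 1L)
  expect_equal(cand$onset, c(1L, 7L))
  expect_equal(cand$offset, c(6L, 13L))
})

test_that("super-threshold sample set shrinks monotonically with lambda", {
  set.seed(21)
  n <- 400
  vel <- fake_vel(rnorm(n, 0, 3), rnorm(n, 0, 2))
  sigma <- robust_sigma(vel)
  sets <- lapply(c(3, 5, 8), function(lam) {
    cand <- threshold_candidates(vel, sigma, lam, min_dur_samples = 1L)
    as.integer(unlist(lapply(seq_len(nrow(cand)), function(i)
      cand$onset[i]:(cand$offset[i] - 1L))))
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
  # brute-force per-sample scan agrees with the run extraction
  for (k in seq_along(c(3, 5, 8))) {
    lam <- c(3, 5, 8)[k]
    brute <- which((vel$vx / (lam * sigma[1]))^2 +
                     (vel$vy / (lam * sigma[2]))^2 > 1)
    expect_identical(sort(sets[[k]]), brute)
  }
})

test_that("fixation ignore windows drop overlapping candidates whole", {
  rate <- 500
  tr <- flat_trace(600, rate)
  # event inside the first 20 ms of the fixation (samples 1..10)
  tr <- inject_step(tr, 5L, 11L, 0.4, 0)
  # event safely inside
  tr <- inject_step(tr, 300L, 310L, 0.4, 0)
  vel <- estimate_velocity(tr, 5L)
  sigma <- robust_sigma(vel)
  fix <- one_fixation(tr)[1, ]
  cand <- threshold_candidates(vel, sigma, 5, 3L,
                               scope = fix$onset:(fix$offset - 1L))
  expect_gte(nrow(cand), 2)
  p <- microsaccade_params(eye_mode = "right")
  ev <- apply_constraints(cand, tr, vel, p, fixation = fix)
  expect_equal(nrow(ev), 1L)
  expect_gte(ev$onset, 11L)  # only the interior event survives
  # with no ignore window both events survive
  p0 <- microsaccade_params(ignore_fix_start_ms = 0, eye_mode = "right")
  expect_equal(nrow(apply_constraints(cand, tr, vel, p0, fixation = fix)), 2L)
})

test_that("amplitude bound drops events exceeding the maximum", {
  tr <- flat_trace(400)
  tr <- inject_step(tr, 150L, 160L, 1.2, 0)  # 1.2 deg displacement
  vel <- estimate_velocity(tr, 5L)
  fix <- one_fixation(tr)[1, ]
  cand <- threshold_candidates(vel, robust_sigma(vel), 5, 3L,
                               scope = fix$onset:(fix$offset - 1L))
  p <- microsaccade_params(eye_mode = "right")  # max amplitude 1 deg
  expect_equal(nrow(apply_constraints(cand, tr, vel, p, fixation = fix)), 0L)
  p2 <- microsaccade_params(max_amp_deg = 2, eye_mode = "right")
  ev <- apply_constraints(cand, tr, vel, p2, fixation = fix)
  expect_equal(nrow(ev), 1L)
  expect_gte(ev$amplitude, 1.1)
})

test_that("minimum ISI keeps the earlier event, verified by brute force", {
  rate <- 500
  # direct brute-force left-to-right scan over synthetic interval lists
  brute_isi <- function(iv, min_isi_ms) {
    keep <- logical(nrow(iv))
    last <- -Inf
    for (i in seq_len(nrow(iv))) {
      onset_t <- (iv$onset[i] - 1) / rate
      if ((onset_t - last) * 1000 >= min_isi_ms - 1e-9) {
        keep[i] <- TRUE
        last <- (iv$offset[i] - 1) / rate
      }
    }
    keep
  }
  # two events 10 ms apart with min ISI 20 ms -> second dropped
  tr <- flat_trace(600)
  tr <- inject_step(tr, 200L, 210L, 0.4, 0)
  tr <- inject_step(tr, 215L, 225L, 0, 0.4)  # onset 10 ms after offset
  vel <- estimate_velocity(tr, 5L)
  fix <- one_fixation(tr)[1, ]
  cand <- threshold_candidates(vel, robust_sigma(vel), 5, 3L,
                               scope = fix$onset:(fix$offset - 1L))
  p <- microsaccade_params(eye_mode = "right",
                           ignore_around_missing_ms = 0)
  ev <- apply_constraints(cand, tr, vel, p, fixation = fix)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$onset - 200L), 4)
  p0 <- microsaccade_params(min_isi_ms = 0, eye_mode = "right")
  expect_equal(nrow(apply_constraints(cand, tr, vel, p0, fixation = fix)), 2L)

  # property: keep/drop decisions equal the brute-force scan
  set.seed(33)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    on <- sort(sample(seq(10, 900, by = 5), k))
    iv <- data.frame(onset = on, offset = on + sample(3:10, k, replace = TRUE))
    iv <- iv[c(TRUE, iv$onset[-1] > iv$offset[-k]), , drop = FALSE]
    keep <- brute_isi(iv, 20)
    # mimic: feed through the same rule used in apply_constraints
    kept <- iv[keep, , drop = FALSE]
    gaps_ms <- (kept$onset[-1] - kept$offset[-nrow(kept)]) / rate * 1000
    if (length(gaps_ms)) expect_true(all(gaps_ms >= 20 - 1e-9))
  }
})

test_that("near-gap candidates are excluded when requested", {
  tr <- flat_trace(600)
  tr$valid[300:310] <- FALSE
  tr <- inject_step(tr, 320L, 330L, 0.4, 0)  # 10 samples (20 ms) after gap
  vel <- estimate_velocity(tr, 5L)
  fix <- one_fixation(tr)[1, ]
  # fixation spans the gap; detection masks velocities inside it anyway
  cand <- threshold_candidates(vel, robust_sigma(vel), 5, 3L,
                               scope = fix$onset:(fix$offset - 1L))
  p_near <- microsaccade_params(ignore_around_missing_ms = 50,
                                eye_mode = "right")
  expect_equal(nrow(apply_constraints(cand, tr, vel, p_near,
                                      fixation = fix)), 0L)
  p_off <- microsaccade_params(ignore_around_missing_ms = 0,
                               eye_mode = "right")
  expect_equal(nrow(apply_constraints(cand, tr, vel, p_off,
                                      fixation = fix)), 1L)
})

test_that("binocular merging pairs overlapping events (identity, disjoint)", {
  tr <- flat_trace(200, eye = "left")
  vel <- estimate_velocity(tr, 5L)
  mk <- function(trc, on, off) {
    fix <- one_fixation(trc)[1, ]
    data.frame(kind = "microsaccade", eye = trc$eye, onset = on, offset = off,
               onset_t = (on - 1) / 500, offset_t = (off - 1) / 500,
               duration_ms = (off - on) * 2, dx = 0.1, dy = 0, amp_x = 0.1,
               amp_y = 0, amplitude = 0.1, peak_velocity = 20,
               direction_deg = 0, fixation_id = 1L,
               t_in_fixation_ms = (on - 1) * 2,
               onset_left = NA_integer_, offset_left = NA_integer_,
               onset_right = NA_integer_, offset_right = NA_integer_)
  }
  l <- mk(tr, 50L, 60L)
  r <- mk(tr, 50L, 60L)
  m <- merge_binocular(l, r, 500)
  expect_equal(nrow(m), 1L)
  expect_equal(m$onset, 50L)
  expect_equal(m$offset, 60L)
  expect_identical(m$eye, "binocular")
  expect_equal(m$onset_left, 50L)
  expect_equal(m$onset_right, 50L)

  # disjoint intervals -> nothing
  expect_equal(nrow(merge_binocular(mk(tr, 50L, 60L), mk(tr, 80L, 90L), 500)),
               0L)
  # partial overlap -> union interval
  m2 <- merge_binocular(mk(tr, 50L, 60L), mk(tr, 55L, 70L), 500)
  expect_equal(m2$onset, 50L)
  expect_equal(m2$offset, 70L)
})

test_that("binocular pairing matches exhaustive maximum matching on small instances", {
  # brute force: maximum-cardinality matching by enumerating all pairings
  max_matching <- function(liv, riv) {
    overlaps <- function(a, b) min(a[2], b[2]) - max(a[1], b[1]) >= 1
    best <- 0
    recur <- function(i, used_r, count) {
      if (i > length(liv)) {
        best <<- max(best, count)
        return()
      }
      recur(i + 1, used_r, count)
      for (j in seq_along(riv)) {
        if (!used_r[j] && overlaps(liv[[i]], riv[[j]])) {
          used_r[j] <- TRUE
          recur(i + 1, used_r, count + 1)
          used_r[j] <- FALSE
        }
      }
    }
    recur(1, rep(FALSE, length(riv)), 0)
    best
  }
  set.seed(91)
  for (rep in 1:30) {
    nl <- sample(1:3, 1)
    nr <- sample(1:3, 1)
    mkiv <- function(k) {
      on <- sort(sample(seq(1, 120, by = 4), k))
      lapply(seq_len(k), function(i) c(on[i], on[i] + sample(3:12, 1)))
    }
    liv <- mkiv(nl)
    riv <- mkiv(nr)
    # drop overlapping-within-eye draws (detector output is disjoint)
    disjoint <- function(iv) all(diff(sapply(iv, `[`, 1)) >
                                   head(sapply(iv, function(v) v[2] - v[1]),
                                        -1) * 0 + 0) &&
      all(head(sapply(iv, `[`, 2), -1) <= tail(sapply(iv, `[`, 1), -1))
    if (length(liv) > 1 && !disjoint(liv)) next
    if (length(riv) > 1 && !disjoint(riv)) next
    got <- length(ref_binocular(liv, riv))
    expect_equal(got, max_matching(liv, riv))
  }
})

test_that("injected microsaccade is found; bounds and eye modes behave", {
  rate <- 500
  n <- 1500
  mk_eye <- function(eye, with_ms) {
    tr <- flat_trace(n, rate, eye = eye)
    if (with_ms) tr <- inject_step(tr, 700L, 706L, 0.35, 0.2)  # 12 ms, ~0.4 deg
    tr
  }
  both <- gaze_trial("t1", list(left = mk_eye("left", TRUE),
                                right = mk_eye("right", TRUE)))
  fix <- one_fixation(both$traces$left)
  ev <- detect_microsaccades(both, fix)
  expect_equal(nrow(ev), 1L)
  expect_lt(ev$onset, 706L)
  expect_gt(ev$offset, 700L)
  expect_equal(ev$fixation_id, 1L)
  expect_equal(ev$t_in_fixation_ms, (ev$onset - 1) * 1000 / rate)

  # raising min duration above the injected duration removes it
  p_long <- microsaccade_params(min_dur_ms = 20)
  expect_equal(nrow(detect_microsaccades(both, fix, p_long)), 0L)

  # left-only injection: binocular finds nothing, monocular-left finds it
  lonly <- gaze_trial("t2", list(left = mk_eye("left", TRUE),
                                 right = mk_eye("right", FALSE)))
  expect_equal(nrow(detect_microsaccades(lonly, fix)), 0L)
  p_left <- microsaccade_params(eye_mode = "left")
  expect_equal(nrow(detect_microsaccades(lonly, fix, p_left)), 1L)

  # requesting an absent eye errors
  ronly <- gaze_trial("t3", list(right = mk_eye("right", TRUE)))
  expect_error(detect_microsaccades(ronly, fix), "binocular")
  expect_error(detect_microsaccades(ronly, fix, p_left), "left")
})

test_that("saccade detection finds large injected movements only", {
  rate <- 500
  tr <- flat_trace(3000, rate)
  tr <- inject_step(tr, 800L, 820L, 5 * cos(0.3), -5 * sin(0.3))
  tr <- inject_step(tr, 2000L, 2020L, -4, 2)
  sac <- detect_saccades(tr)
  expect_equal(nrow(sac), 2L)
  expect_lt(abs(sac$onset[1] - 800), 6)
  expect_lt(abs(sac$onset[2] - 2000), 6)
  expect_true(all(sac$amplitude >= 1))
  # pure drift trace -> nothing (1 deg minimum amplitude suppresses it)
  expect_equal(nrow(detect_saccades(flat_trace(3000, rate))), 0L)
})

test_that("fixations are the complement of saccades minus gaps", {
  rate <- 500
  tr <- flat_trace(3000, rate)
  tr <- inject_step(tr, 800L, 820L, 5, -1)
  tr <- inject_step(tr, 2000L, 2020L, -4, 2)
  sac <- detect_saccades(tr)
  fx <- derive_fixations(tr, sac)
  expect_equal(nrow(fx), 3L)
  expect_equal(fx$onset[1], 1L)
  expect_equal(fx$offset[3], 3001L)
  expect_equal(fx$onset[2], sac$offset[1])
  expect_equal(fx$offset[2], sac$onset[2])
  # zero saccades -> one fixation spanning the trace
  fx0 <- derive_fixations(tr, sac[0, ])
  expect_equal(nrow(fx0), 1L)
  expect_equal(c(fx0$onset, fx0$offset), c(1L, 3001L))
  # centroid equals the mean of valid samples in span
  expect_equal(fx0$cx, mean(tr$x))

  # gaps abutting saccades: brute-force set subtraction oracle
  tr$valid[810:850] <- FALSE
  sac2 <- detect_saccades(tr)
  fx2 <- derive_fixations(tr, sac2, min_samples = 5L)
  free <- rep(TRUE, 3000)
  if (nrow(sac2)) {
    for (i in seq_len(nrow(sac2))) free[sac2$onset[i]:(sac2$offset[i] - 1)] <- FALSE
  }
  free[!tr$valid] <- FALSE
  oracle <- msdetect:::index_runs(which(free))
  oracle <- oracle[(oracle$offset - oracle$onset) >= 5, ]
  expect_equal(fx2$onset, oracle$onset)
  expect_equal(fx2$offset, oracle$offset)
})

test_that("averaging eyes is the sample-wise mean with AND validity", {
  l <- gaze_trace(c(1, 1, 2), c(1, 1, 2), 500, eye = "left")
  r <- gaze_trace(c(3, 3, 4), c(3, 3, 4), 500, eye = "right")
  a <- average_eyes(l, r)
  expect_equal(a$x, c(2, 2, 3))
  expect_equal(a$y, c(2, 2, 3))
  expect_identical(a$eye, "averaged")
  # identical traces -> identical output
  a2 <- average_eyes(l, l)
  expect_equal(a2$x, l$x)
  # invalid on one side poisons the sample
  r$valid[2] <- FALSE
  expect_equal(average_eyes(l, r)$valid, c(TRUE, FALSE, TRUE))
  expect_error(average_eyes(l, gaze_trace(1:5, 1:5, 500)), "length")
})

test_that("detected events satisfy every active bound and stay inside fixations", {
  cfg <- short_sim_config(glissade_prob = 0.5)
  p <- microsaccade_params()
  for (seed in 1:5) {
    r <- simulate_trial(cfg, seed = 400 + seed)
    res <- analyze_trial(r$trial, p, refit_fixations = TRUE)
    ev <- res$microsaccades
    fx <- res$fixations
    if (nrow(ev) == 0) next
    expect_true(all(ev$duration_ms >= p$min_dur_ms))
    expect_true(all(ev$amplitude <= p$max_amp_deg))
    for (i in seq_len(nrow(ev))) {
      f <- fx[fx$fixation_id == ev$fixation_id[i], ]
      expect_gte(ev$onset[i], f$onset)
      expect_lte(ev$offset[i], f$offset)
      expect_gte(ev$t_in_fixation_ms[i], p$ignore_fix_start_ms)
    }
    # inter-event gaps within a fixation respect the minimum ISI
    for (id in unique(ev$fixation_id)) {
      e <- ev[ev$fixation_id == id, ]
      if (nrow(e) > 1) {
        gaps <- (e$onset_t[-1] - e$offset_t[-nrow(e)]) * 1000
        expect_true(all(gaps >= p$min_isi_ms - 1e-9))
      }
    }
    # range-based amplitude is at least the displacement norm
    expect_true(all(ev$amplitude >= sqrt(ev$dx^2 + ev$dy^2) - 1e-12))
  }
})
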
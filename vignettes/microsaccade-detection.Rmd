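---
title: "Velocity-threshold microsaccade detection: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Velocity-threshold microsaccade detection: model, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdetect)
```

## The detection model

Microsaccades are small (typically below 1 degree of visual angle),
fast, involuntary eye movements that occur within fixations.
Kinematically they are miniature saccades: brief, ballistic, and
obeying the same lawful amplitude/peak-velocity relationship (the
"main sequence").  `msdetect` implements the classical adaptive
velocity-threshold approach for their detection, extended with the
conditional constraints that published studies commonly layer on top
of it, so that every analysis choice is an explicit, recorded
parameter rather than a hard-coded convention.

The pipeline for one eye is:

1. **Velocity estimation.**  Gaze position (in visual degrees) is
   differentiated with a weighted central-difference stencil over a
   window of `w = 2m + 1` samples:
   \[
     v_n \;=\; \frac{\sum_{k=1}^{m} (x_{n+k} - x_{n-k})}
                    {2\,\Delta t \sum_{k=1}^{m} k},
   \]
   which for the default `w = 5` reduces to the familiar form
   \((x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2}) / (6\Delta t)\).  The
   stencil is exact for affine trajectories at every window size (the
   generalization is needed because the window size itself is an
   exposed parameter).  Velocities whose stencil touches a trace edge
   or a missing-data sample are *undefined*, never interpolated:
   position samples adjacent to gaps are untrustworthy and runs of
   super-threshold samples must not bridge them.

2. **Robust dispersion.**  Per axis,
   \(\sigma = \sqrt{\operatorname{median}(v^2) -
   \operatorname{median}(v)^2}\) — a median-based analogue of the
   standard deviation that is insensitive to exactly the rare
   high-velocity excursions the threshold is meant to find.  A
   dispersion below \(10^{-10}\) °/s on either axis raises a
   degenerate-signal error (constant or duplicated data); note that
   this estimator is *scale*-equivariant but not exactly invariant
   under shifting all velocities by a constant, which is immaterial in
   practice because fixational velocity distributions are centred near
   zero.

3. **Elliptic threshold.**  A sample is super-threshold when
   \((v_x/\lambda\sigma_x)^2 + (v_y/\lambda\sigma_y)^2 > 1\)
   (strictly).  Maximal runs of super-threshold, defined samples of at
   least the minimum duration become candidate events.

4. **Constraints.**  In order: candidates overlapping the ignored
   window at a fixation's start or end are dropped *whole* (a trimmed
   glissade fragment would masquerade as a short microsaccade, so
   trimming is never correct); candidates near missing data are
   dropped when that exclusion is enabled; kinematics are computed and
   duration/amplitude/peak-velocity bounds applied; finally a left-to-
   right scan discards any event starting less than the minimum
   inter-saccadic interval after the previous kept event's offset —
   dropping the later event rather than merging, because such
   followers are typically overshoot artifacts, not new movements.

5. **Binocular merging** (default).  Detection runs independently in
   both eyes; only pairs of events with at least one sample of
   temporal overlap survive, paired greedily by largest overlap (ties
   broken toward the earlier right-eye event).  The merged interval is
   the union of the pair; headline kinematics are the mean of the two
   eyes (directions: circular mean), with per-eye intervals retained.
   Requiring binocular coincidence trades a little sensitivity for a
   large specificity gain against monocular sensor noise — the reason
   monocular detection reliably reports *more* events on noisy data.

Event kinematics follow the conventions of the reference velocity-
threshold literature: the amplitude is the norm of the sign-carrying
per-axis coordinate ranges over the event (which bounds the start-to-
end displacement norm from above), the direction is taken from the
start-to-end displacement, and the peak velocity is the maximum speed
within the event.  Directions use screen conventions with 0° =
rightward and 90° = up on screen (screen y grows downward and is
flipped for angular measures).

**Saccades and fixations.**  The saccade filter is the *same*
pipeline run over the whole trial with its own defaults (below); its
1° minimum amplitude suppresses fixational events.  Fixations are then
simply the complement: the intervals between consecutive saccades
(including trial start/end pieces), minus missing-data ranges, with
intervals shorter than one velocity window discarded.  Fixation
centroids are the means of the valid samples in the span.

## Parameters and defaults

| Parameter | Microsaccade filter | Saccade filter |
|---|---|---|
| λ (threshold multiplier, unitless) | 5 | 8 |
| minimum duration | 6 ms | 3 ms |
| velocity window | 5 samples | 9 samples |
| amplitude bounds | max 1° | min 1° |
| minimum inter-saccadic interval | 20 ms | 50 ms |
| ignored fixation start | 20 ms | — |
| eye mode | binocular | averaged trace |

These are the configuration most widely reused by studies of
microsaccades in 500 Hz binocular recordings.  Every other bound
(duration/amplitude/peak-velocity minima and maxima, ignored fixation
end, exclusion near missing data) defaults to "off" and exists because
some published analysis used it; the package's purpose is to make
such choices explicit and sweepable (`run_cli("sweep", ...)`).

Two genuinely open design points deserve a note:

- **Dispersion scope.**  Published descriptions do not pin down
  whether σ is estimated per fixation or per trial.  The default here
  pools all fixation samples of a trial (`sigma_scope = "trial"`),
  which is the more stable estimate — short fixations can contain too
  few defined velocity samples for a meaningful median.  A
  per-fixation option (`"fixation"`) is provided; fixations whose
  dispersion cannot be estimated are then silently skipped.
- **Ignore-window overlap.**  Whether candidates partially
  overlapping an ignored window should be trimmed or dropped is not
  specified anywhere; they are dropped whole, for the reason given
  above.

## The synthetic generator

Real microsaccade data sets are rarely redistributable, so the
package ships a seeded generator that produces labeled traces
exhibiting every phenomenon the detector must handle, and the test
suite and acceptance script validate the implementation against that
ground truth.  One trial is assembled as:

- a scanpath of fixations (uniform 0.8–2 s — long, stable fixations
  typical of sustained viewing, long enough to host microsaccades)
  alternating with 3–8° saccades of 30–50 ms;
- microsaccades injected inside fixations at 1.5 events/s with
  amplitudes 0.1–0.8°, no closer than 60 ms to the fixation onset,
  40 ms to its end, or 120 ms to each other (a refractory spacing
  consistent with observed inter-microsaccade intervals);
- each movement realized with a raised-cosine velocity profile, which
  gives the closed-form relation peak velocity = 2·amplitude/duration
  and lets the generator enforce a main-sequence law
  \(V = k A^{p}\) (defaults k = 60, p = 1, durations clipped to
  6–30 ms) analytically;
- optional post-saccadic glissades: with probability 0.5 a saccade
  overshoots its target by 10 % of its amplitude and returns over
  15–35 ms immediately after the saccade — the canonical confound
  that masquerades as a microsaccade at fixation onset;
- fixational drift as a shared 2D random walk (step SD 0.001°/sample,
  i.e. ≈0.02° RMS excursion per second at 500 Hz), sensor dropouts
  (0.02/s, 40–150 ms), and finally per-eye independent Gaussian noise
  (SD 0.01°, the precision class of a tower-mounted research tracker)
  on top of the shared binocular signal.

Each phenomenon draws from its own RNG substream, so toggling one
(e.g. disabling glissades) leaves every other phenomenon's
realization bit-identical — which is what makes contrasts such as
"same trial with and without glissades" meaningful.

What the generator does **not** emulate: tremor spectra, smooth
pursuit, blink dynamics (dropouts are clean gaps, not blink
artifacts), square-wave jerks, saccadic curvature, or any
oculomotor-plant dynamics.  Passing tests therefore demonstrate
algorithmic correctness and calibration on idealized signals, not
performance on any particular real tracker's noise.

## Validation design

The package's correctness argument has three independent legs, all
executed by the test suite (`tests/testthat/`) and re-run from scratch
by `scripts/acceptance.R`:

1. **Oracle equivalence.**  A deliberately naive reference
   implementation (per-sample threshold scans, explicit loops,
   exhaustive pairing) lives beside the tests and must reproduce the
   pipeline's saccade, fixation, and microsaccade intervals *exactly*
   on 100 seeded random trials.
2. **Ground-truth recovery.**  On a 20-trial, 500 Hz, 15 s cohort
   with 0.2–0.8° microsaccades of 8–25 ms over the default
   drift/noise, the default detector must reach precision and recall
   of at least 0.90 against the injected events at 4 ms onset
   tolerance.  This cohort is generated with glissades and dropouts
   disabled: it measures detector accuracy on true microsaccades,
   while glissade confusion is measured separately (next item).  With
   all defaults the generator's smallest events (0.1°) sit at the
   detection floor by design — at 60°/s per degree their peak
   velocities are ≈6°/s, comparable to the λσ threshold under default
   noise — so the default cohort exercises the boundary rather than
   hiding it.
3. **Mechanism contrasts.**  With glissades injected after every
   saccade and fixations taken from ground truth (the situation when
   fixations come precomputed from tracker software), the 40 ms
   temporal-position histogram shows a first-bin excess of at least
   2× the second bin when no fixation-start window is ignored, the
   excess disappears once the ignored window covers the glissade
   durations, and no true microsaccade that was detected without the
   window is lost with it.  Alongside: super-threshold sample sets
   are nested across λ ∈ {3, 5, 8, 10}, binocular event counts never
   exceed either monocular count, and write→read round trips are
   lossless.

Problem sizes (trial lengths of 3 s for the oracle and contrast
cohorts, 15 s for the accuracy cohort; 5–100 trials per property) were
chosen to give each property hundreds of events while keeping the
whole suite fast to iterate.

## Numerical choices and edge cases

- Timestamps are represented as sample index over rate (plus a trial
  start time), so file round trips are exact; positions are written
  at full (17 significant digit) precision.
- Event intervals are half-open `[onset, offset)` in sample indices —
  1-based inside R, 0-based in files.
- Strict inequality on the ellipse test: a sample exactly on the
  threshold boundary is *not* super-threshold.
- Millisecond parameters are converted to samples conservatively
  (durations round up, ignore windows round down) with a 1e-9 guard
  against floating-point edge effects, so e.g. 6 ms at 500 Hz is
  exactly 3 samples on both sides of the comparison.
- The dispersion estimator requires at least 10 defined samples in
  scope and errors on degenerate (constant) signals rather than
  returning a zero threshold.
- Empty inputs flow through: empty event lists produce valid files,
  zero-count histograms, and `NA`-flagged circular means.

## Known limitations

- The pixel-to-degree conversion assumes a fixed viewing distance on
  the screen-centre normal; per-sample 3D eye positions are not
  supported.
- Blink reconstruction, smoothing, and other pre-processing are out
  of scope; data are expected clean apart from missing-data gaps.
- Square-wave-jerk labeling is not implemented; a jerk's two phases
  will appear as two opposite-direction microsaccades subject to the
  inter-saccadic-interval rule.
- Condition-level aggregation pools raw events across trials (a
  documented choice — it equals recomputation from the pooled event
  list); per-participant-mean aggregation can be obtained by
  aggregating at participant level and averaging externally.
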
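---
title: "Closed-loop movement sonification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop movement sonification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachtone)
```

# The system

reachtone is a hardware-free implementation of a closed-loop auditory
feedback system for head-fixed mouse forelimb reaching, together with the
offline analysis used to quantify the motor learning it promotes. The
processing chain per video frame is:

1. **Pose acquisition.** A markerless pose estimator supplies, per frame,
   (x, y, likelihood) for each of eight keypoints: four digits per
   forepaw. In this package the estimator is replaced by a pose-source
   interface: replay of a pose CSV, or the behavior simulator. Image
   convention: y increases downward.
2. **Displacement extraction.** Per paw, digits whose likelihood passes a
   confidence floor are averaged (mean y); vertical displacement is
   `(rest_y - y) * mm_per_pixel`, so upward motion is positive. If no
   digit passes the floor, the frame is invalid and holds the last valid
   displacement — dropping frames would stall both the trial logic and
   the tone.
3. **Smoothing.** A short causal moving average stabilizes displacement
   before it reaches the trial machine and the sonifier. A causal filter
   adds no algorithmic look-ahead, which matters in a closed loop.
4. **Trial state machine.** AT_REST → REACHING when displacement exceeds
   the resting band (`start_tolerance`); a REACHING trajectory that
   crosses `target_offset` (the target zone ~15 mm above rest) emits
   `target_entry`, `success` and a 5 µl `reward`, and enters REFRACTORY;
   the machine re-arms only when the paw has returned to the resting band
   *and* the refractory interval has elapsed — the behavioral rule that
   the paw must return to its initial resting position before the next
   trial.
5. **Sonification.** In feedback mode, each frame's smoothed left-paw
   displacement maps linearly onto tone frequency,
   `f = f_min + (f_max − f_min) · clip(d / d_max, 0, 1)`, with
   `f_min = 2 kHz`, `f_max = 20 kHz` and `d_max` equal to the 15 mm
   target. Control mode runs the identical loop but emits no tone
   commands; the tone log is the *only* difference between modes, which
   the tests assert.

Audio itself is rendered offline by `synthesize()`: a phase-accumulator
sine with zero-order-hold frequency between commands and raised-cosine
amplitude ramps (5 ms), so frequency steps are click-free. Real-time
audio callbacks, cameras, reward dispensers and the LED are out of scope;
the LED is a logged boolean only.

# Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `target_offset` | 15 | mm | target-zone height above rest |
| `start_tolerance` | 2 | mm | resting band; hysteresis far below the target prevents trial chatter from tracking noise. The behavioral protocol specifies a return to rest without a numeric band; 2 mm is this package's choice |
| `refractory` | 0.5 | s | minimum post-success inter-trial interval; the protocol specifies return-to-start but no minimum interval |
| `likelihood_floor` | 0.6 | — | confidence gate on keypoints |
| `smooth_window` | 3 | frames | ~43 ms at 70 fps; short enough not to blunt reach apexes |
| `reward_ul` | 5 | µl | water reward per success |
| `f_min`, `f_max` | 2, 20 | kHz | speaker-rated band that still overlaps the mouse's audible sensitivity peak (10–20 kHz) |
| `d_max` | 15 | mm | the target height maps to `f_max`, so the top of the band signals target entry |
| `ramp_ms` | 5 | ms | raised-cosine on/off ramps; avoids audible clicks that would themselves act as feedback |

Aggregating digits by mean (rather than median) was chosen for
smoothness; with four digits per paw the difference is minor. Mapping
input is displacement-from-rest rather than absolute pixel position, and
displacement outside `[0, d_max]` is clipped rather than extrapolated,
keeping output inside the speaker-rated band.

# The behavior simulator

`simulate_session()` / `simulate_cohort()` generate the study design —
two groups (feedback, control) of 7 mice, one 30-minute session per day
for 4 days at 70 fps — with planted learning:

* **Reach kinematics.** Each reach is a minimum-jerk position profile
  (`10u³ − 15u⁴ + 6u⁵`) rising to its apex and mirroring back, rescaled
  so the sampled maximum equals the drawn apex exactly, plus optional
  Gaussian jitter. The real trajectory distribution is not published;
  the minimum-jerk template is the standard fully-specified model of
  smooth point-to-point limb movement.
* **Learning dynamics.** Left-paw reach rate starts at 2/min and grows
  per day by ×1.35 (feedback) vs ×1.10 (control); apexes are drawn from
  N(16, 3) mm with the SD shrinking by ×0.8 per day in the feedback
  group, so learning is planted both in rate (the reach-ratio phenomenon)
  and in trajectory consistency (the day-1-vs-later cluster structure).
  The right paw reaches at a constant 2/min and only provides the
  denominator of the reach ratio. All of these values are stand-ins
  chosen to be realistic for water-restricted head-fixed mice; no
  distributional parameters are reported for the real animals.
* **Pixel plumbing.** Displacement is converted to pixel-space keypoints
  through an internal calibration (0.1 mm/px, rest at y = 300), with the
  four digit offsets symmetric about the paw centroid, so the full
  pixel→mm code path is exercised. A small per-digit dropout rate (1%)
  plants low-confidence keypoints to exercise the gating/hold-last path.
* **Scheduling.** Reach onsets follow a Poisson process thinned to a
  minimum 1 s rest gap, which keeps every planted reach a countable
  attempt (the gap exceeds the 0.5 s refractory), making the simulator's
  ground truth and the engine's event stream exactly comparable on
  noise-free streams — an oracle-equivalence the tests assert.

What the simulator does **not** emulate: closed-loop behavioral
plasticity (the simulated animal does not hear the tone; the learning
gains are imposed, not emergent), tracking failures correlated with
posture, camera distortion, paw occlusions, or non-stationary motivation
within a session. Passing tests therefore demonstrate that the pipeline
measures planted effects correctly, not that real mice behave this way.

# Offline analysis

Reaches are segmented offline as maximal excursions above
`start_tolerance` — the same counting rule as the real-time machine, but
without refractory logic, which cannot suppress counts on simulated data
because planted reaches are separated by more than the refractory. Each
reach is linearly time-warped to a common length (default 100 samples),
forming the trajectory matrix for:

* **PCA** (mean-centered); clustering uses the smallest number of
  components explaining ≥90% of variance. The source analyses name
  "main principal components" without a count; 90% is this package's
  choice.
* **GMM + BIC**: full-covariance Gaussian mixtures fitted per candidate
  K (default 1–6), selecting the K that minimizes BIC
  (−2 log L + p log n). Fitting is delegated to mclust, whose
  model-based hierarchical initialization is deterministic — this
  replaces the more common multiple-random-restart scheme with a
  reproducible equivalent.
* **t-SNE** (exact, in-package: perplexity calibration by bisection,
  momentum gradient descent, early exaggeration) is quarantined to
  visualization; no clustering decision uses it.
* **Reach ratio**: per mouse and day, left-paw reaches / right-paw
  reaches, normalized to the mouse's Day-1 ratio. Day 1 is identically 1
  by construction; consequently per-day group tests and the
  repeated-measures ANOVA use Days ≥ 2 (the source analyses likewise
  test Days 2–4). Mice with a zero right-paw count or zero Day-1 ratio
  cannot be normalized and are excluded with a report.
* **Statistics**: per-day unpaired two-sample tests (Welch by default;
  pooled-variance available), Cohen's d (mean difference over pooled SD,
  feedback minus control), and a two-way repeated-measures ANOVA (day
  within-subject, group between-subject) via `car::Anova`, with
  Greenhouse–Geisser-corrected p-values for within-subject terms. With
  only two within-subject levels sphericity is trivial and no correction
  is reported.

`simulate_ratio_cohort()` generates cohorts directly at the level of the
learning metric (per-mouse random intercepts + day noise, optional
planted group effect in pooled-SD units). It exists to calibrate the
statistics cheaply: under the null the per-day tests and the ANOVA group
effect reject at ~5%, and a planted 2-SD effect at n = 7/group is
detected with ≥80% power — both asserted over 200 simulations in the
test suite.

# Numerical and degenerate-input choices

* Pose CSV numerics are written with 17 significant digits, so
  write→read round trips are exact to double precision.
* Missing or non-finite pose cells become keypoints with likelihood 0
  (not dropped frames), preserving loop cadence; a finite likelihood
  outside [0, 1] is a hard validation error naming frame and bodypart.
  The four-header multi-animal CSV dialect is detected and rejected.
* End-to-end latency is reported as the per-frame sum of stage timings
  (acquire, kinematics, fsm, tone), which under the simulated clock
  equals the tone-command minus frame-delivery timestamp difference; the
  tests assert both the exactness of the former and the agreement of the
  latter to 1e-9. Wall-clock hardware numbers (>70 Hz, ~30 ms) are
  instrumentation targets, not claims this package can make.
* A single sample jumping from rest past the target yields
  `reach_start` and the success events in the same frame (threshold
  crossings are evaluated in cascade within a sample).
* Session-audio validation windows are the tone-command hold intervals:
  the synthesizer holds frequency constant between commands, so each
  window contains a pure tone and its FFT peak is comparable to the
  commanded frequency at one-bin resolution (`sample_rate / n_samples`).
  A general fixed-window `spectrogram_peak_track()` is provided for pure
  tones and chirps; validation is on the linear-frequency spectrum (a
  mel display changes the axis, not the peak comparison).
* Correlation between tone frequency and movement pairs each active
  command with the concurrent smoothed displacement (nearest timestamp
  within one frame period) and uses only unclipped pairs
  (0 < d < `d_max`), where the map is affine — so the noise-free
  correlation is exactly 1. "Movement intensity" is interpreted as
  instantaneous vertical displacement.
* Reaches of a single sample cannot be time-warped and are excluded from
  the trajectory matrix with a counted warning.

# Problem sizes

Simulated sessions in the test suite are 5–180 s (at the full 70 fps)
rather than 30 min — the phenomena under test (event grammar, oracle
equivalence, determinism) are length-invariant. The acceptance script
uses the full 7 + 7 × 4-day design with 600 s sessions for the cohort
statistics, 30 seeded two-cluster sets for the clustering recovery, and
200 simulations each for null calibration and power. The clustering
acceptance check in the test suite uses 100 seeded sets of 60
trajectories.

# Known limitations

* The engine consumes pre-recorded or simulated streams; it measures its
  own stage latencies but cannot demonstrate hardware latency.
* The simulator's learning parameters are stand-ins; effect sizes and
  p-values computed on simulated cohorts characterize the pipeline, not
  the biology.
* `detect_reaches` without refractory logic can disagree with the
  real-time machine on pathological streams (reaches packed closer than
  the refractory); on such data the event log is authoritative.
* Exact t-SNE is O(n²) per iteration and intended for at most a few
  thousand trajectories.
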
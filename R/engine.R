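#' Trial configuration
#'
#' Parameters of the reaching task and of the real-time processing chain.
#' The target zone sits `target_offset` mm above the resting position
#' (default 15 mm); a reach attempt begins when the left paw rises above
#' `start_tolerance` (a hysteresis band well below the target, so tracking
#' chatter around rest does not spawn trials); after a success the trial
#' machine stays refractory for at least `refractory` seconds and until the
#' paw has returned to within `start_tolerance` of rest. Keypoints with
#' likelihood below `likelihood_floor` are ignored when aggregating digit
#' positions into a paw position; a causal moving average of
#' `smooth_window` frames stabilizes the displacement before it reaches
#' the state machine and the sonifier.
#'
#' @param target_offset target-zone height above rest (mm).
#' @param start_tolerance resting band half-width (mm); must be below
#'   `target_offset`.
#' @param refractory minimum post-success interval before a new trial (s).
#' @param likelihood_floor confidence gate for keypoints, in `[0, 1]`.
#' @param smooth_window causal moving-average length (frames), >= 1.
#' @param reward_ul water reward volume per success (microlitres).
#' @param left_digits,right_digits bodypart names making up each paw;
#'   `NULL` selects bodyparts whose names start with `left`/`right`.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(target_offset = 15, start_tolerance = 2,
                         refractory = 0.5, likelihood_floor = 0.6,
                         smooth_window = 3, reward_ul = 5,
                         left_digits = NULL, right_digits = NULL) {
  if (!(target_offset > start_tolerance)) stop("target_offset must exceed start_tolerance")
  if (start_tolerance < 0) stop("start_tolerance must be >= 0")
  if (refractory < 0) stop("refractory must be >= 0")
  if (likelihood_floor < 0 || likelihood_floor > 1)
    stop("likelihood_floor must be in [0, 1]")
  if (smooth_window < 1) stop("smooth_window must be >= 1")
  if (reward_ul <= 0) stop("reward_ul must be > 0")
  structure(list(target_offset = target_offset,
                 start_tolerance = start_tolerance, refractory = refractory,
                 likelihood_floor = likelihood_floor,
                 smooth_window = as.integer(smooth_window),
                 reward_ul = reward_ul, left_digits = left_digits,
                 right_digits = right_digits), class = "trial_config")
}

paw_digits <- function(bodyparts, cfg) {
  left <- cfg$left_digits %||% grep("^left", bodyparts, value = TRUE)
  right <- cfg$right_digits %||% grep("^right", bodyparts, value = TRUE)
  if (!length(left) || !length(right))
    stop("could not identify left/right digit sets among: ",
         paste(bodyparts, collapse = ", "))
  missing <- setdiff(c(left, right), bodyparts)
  if (length(missing))
    stop("configured digits absent from stream: ", paste(missing, collapse = ", "))
  list(left = left, right = right)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Last-observation-carried-forward with a given initial value.
locf <- function(v, initial = 0) {
  ok <- !is.na(v)
  idx <- cumsum(ok)
  c(initial, v[ok])[idx + 1L]
}

#' Extract per-frame paw displacement from a pose stream
#'
#' For each paw and frame, the paw position is the mean y of the digits
#' whose likelihood passes the confidence floor; vertical displacement is
#' `(rest_y - y) * mm_per_pixel`, positive upward. Frames where no digit
#' passes the floor are invalid: they hold the last valid displacement
#' (initially 0) and carry `valid = FALSE`, preserving the loop cadence.
#'
#' @param stream a [pose_stream()].
#' @param cal a [calibration()].
#' @param cfg a [trial_config()].
#' @return A data frame (one row per frame): `t`, `disp_left`,
#'   `disp_right` (mm), `valid_left`, `valid_right`.
#' @export
stream_kinematics <- function(stream, cal, cfg = trial_config()) {
  if (!inherits(cal, "calibration")) stop("a calibration is required")
  dg <- paw_digits(stream$bodyparts, cfg)
  agg <- function(cols, rest_y) {
    yy <- stream$y[, cols, drop = FALSE]
    pass <- stream$likelihood[, cols, drop = FALSE] >= cfg$likelihood_floor &
      is.finite(yy)
    yy[!pass] <- 0
    npass <- rowSums(pass)
    ybar <- ifelse(npass > 0, rowSums(yy) / npass, NA_real_)
    disp <- (rest_y - ybar) * cal$mm_per_pixel
    list(disp = locf(disp, 0), valid = npass > 0)
  }
  L <- agg(dg$left, cal$rest_y_left)
  R <- agg(dg$right, cal$rest_y_right)
  data.frame(t = stream$time, disp_left = L$disp, disp_right = R$disp,
             valid_left = L$valid, valid_right = R$valid)
}

#' Displacement of a single pose frame
#'
#' Per-frame counterpart of [stream_kinematics()] for closed-loop use:
#' computes one `KinematicSample` given the previous sample (for the
#' hold-last rule when all digits fail the confidence floor).
#'
#' @param frame a single frame, as returned by [get_frame()].
#' @param cal a [calibration()].
#' @param cfg a [trial_config()].
#' @param prev previous sample (list with `disp_left`, `disp_right`), or
#'   `NULL` at the stream head (holds 0).
#' @return A list: `t`, `disp_left`, `disp_right`, `valid_left`,
#'   `valid_right`.
#' @export
compute_displacement <- function(frame, cal, cfg = trial_config(),
                                 prev = NULL) {
  if (!inherits(cal, "calibration")) stop("a calibration is required")
  dg <- paw_digits(frame$bodyparts, cfg)
  one <- function(cols, rest_y, prev_disp) {
    lk <- frame$likelihood[cols]
    yy <- frame$y[cols]
    pass <- lk >= cfg$likelihood_floor & is.finite(yy)
    if (!any(pass)) return(list(disp = prev_disp, valid = FALSE))
    list(disp = (rest_y - mean(yy[pass])) * cal$mm_per_pixel, valid = TRUE)
  }
  L <- one(dg$left, cal$rest_y_left, prev$disp_left %||% 0)
  R <- one(dg$right, cal$rest_y_right, prev$disp_right %||% 0)
  list(t = frame$time, disp_left = L$disp, disp_right = R$disp,
       valid_left = L$valid, valid_right = R$valid)
}

#' Causal moving-average smoothing
#'
#' Averages each sample with the preceding `window - 1` samples (fewer at
#' the stream head), adding no delay beyond the window itself; `window = 1`
#' is the identity.
#'
#' @param v numeric vector.
#' @param window window length in frames, >= 1.
#' @return Smoothed numeric vector, same length.
#' @export
smooth_causal <- function(v, window) {
  if (window < 1) stop("window must be >= 1")
  window <- as.integer(window)
  if (window == 1 || length(v) <= 1) return(v)
  cs <- cumsum(v)
  n <- length(v)
  lead <- pmin(seq_len(n), window)
  out <- (cs - c(rep(0, window), head(cs, n - window))[seq_len(n)]) / lead
  out
}

#' Smooth the displacement columns of a kinematic stream
#'
#' Applies [smooth_causal()] to `disp_left` and `disp_right`, appending
#' `disp_left_smooth` / `disp_right_smooth` columns.
#'
#' @param kin kinematic data frame from [stream_kinematics()].
#' @param window window length (frames).
#' @return `kin` with smoothed columns added.
#' @export
smooth_kinematics <- function(kin, window) {
  kin$disp_left_smooth <- smooth_causal(kin$disp_left, window)
  kin$disp_right_smooth <- smooth_causal(kin$disp_right, window)
  kin
}

# ---- trial state machine ---------------------------------------------------

#' Fresh trial-FSM state
#' @return A list: `phase` (`AT_REST`), `refractory_until`, `n_success`.
#' @export
fsm_state <- function() list(phase = "AT_REST", refractory_until = -Inf,
                             n_success = 0L)

#' Advance the trial state machine by one kinematic sample
#'
#' Phases: `AT_REST` -> `REACHING` (emitting `reach_start`) when the left
#' paw rises above `start_tolerance`; in `REACHING`, crossing
#' `target_offset` emits `target_entry`, `success` and `reward` (volume
#' `reward_ul`) and enters `REFRACTORY`, while sinking back to within
#' `start_tolerance` without reaching the target emits `trial_reset` only;
#' `REFRACTORY` -> `AT_REST` (emitting `trial_reset`) once the paw is back
#' within `start_tolerance` AND the refractory interval has elapsed. A
#' sample with `valid_left = FALSE` causes no transition. A single sample
#' that jumps from rest past the target yields `reach_start` and the
#' success events together.
#'
#' @param state FSM state from [fsm_state()] or a previous step.
#' @param sample kinematic sample: list/row with `t`, `disp_left`,
#'   `valid_left`.
#' @param cfg a [trial_config()].
#' @return A list: `state` (updated) and `events` (data frame with `t`,
#'   `kind`, `payload`; possibly zero rows).
#' @export
step_trial_fsm <- function(state, sample, cfg = trial_config()) {
  kinds <- character(0); payloads <- numeric(0)
  t <- sample$t; d <- sample$disp_left
  if (isTRUE(sample$valid_left)) {
    if (state$phase == "AT_REST" && d > cfg$start_tolerance) {
      kinds <- c(kinds, "reach_start"); payloads <- c(payloads, NA_real_)
      state$phase <- "REACHING"
    }
    if (state$phase == "REACHING") {
      if (d >= cfg$target_offset) {
        kinds <- c(kinds, "target_entry", "success", "reward")
        payloads <- c(payloads, NA_real_, NA_real_, cfg$reward_ul)
        state$phase <- "REFRACTORY"
        state$refractory_until <- t + cfg$refractory
        state$n_success <- state$n_success + 1L
      } else if (d <= cfg$start_tolerance) {
        kinds <- c(kinds, "trial_reset"); payloads <- c(payloads, NA_real_)
        state$phase <- "AT_REST"
      }
    } else if (state$phase == "REFRACTORY" &&
               d <= cfg$start_tolerance && t >= state$refractory_until) {
      kinds <- c(kinds, "trial_reset"); payloads <- c(payloads, NA_real_)
      state$phase <- "AT_REST"
    }
  }
  list(state = state,
       events = data.frame(t = rep(t, length(kinds)), kind = kinds,
                           payload = payloads))
}

# Vectorized-bookkeeping FSM over a whole kinematic stream; same semantics
# as step_trial_fsm, loop kept lean for long sessions.
run_trial_fsm <- function(t, disp, valid, cfg, event_t_offset = 0) {
  n <- length(disp)
  cap <- 64L
  ev_t <- numeric(cap); ev_k <- character(cap); ev_p <- numeric(cap)
  m <- 0L
  push <- function(tt, kk, pp) {
    if (m == cap) {
      cap <<- cap * 2L
      length(ev_t) <<- cap; length(ev_k) <<- cap; length(ev_p) <<- cap
    }
    m <<- m + 1L
    ev_t[m] <<- tt; ev_k[m] <<- kk; ev_p[m] <<- pp
  }
  phase <- 0L  # 0 AT_REST, 1 REACHING, 2 REFRACTORY
  refr_until <- -Inf
  tol <- cfg$start_tolerance; tgt <- cfg$target_offset
  for (i in seq_len(n)) {
    if (!valid[i]) next
    d <- disp[i]; ti <- t[i] + event_t_offset
    if (phase == 0L && d > tol) {
      push(ti, "reach_start", NA_real_)
      phase <- 1L
    }
    if (phase == 1L) {
      if (d >= tgt) {
        push(ti, "target_entry", NA_real_)
        push(ti, "success", NA_real_)
        push(ti, "reward", cfg$reward_ul)
        phase <- 2L
        refr_until <- t[i] + cfg$refractory
      } else if (d <= tol) {
        push(ti, "trial_reset", NA_real_)
        phase <- 0L
      }
    } else if (phase == 2L && d <= tol && t[i] >= refr_until) {
      push(ti, "trial_reset", NA_real_)
      phase <- 0L
    }
  }
  data.frame(t = ev_t[seq_len(m)], kind = ev_k[seq_len(m)],
             payload = ev_p[seq_len(m)])
}

# ---- session loop ----------------------------------------------------------

#' Run one closed-loop session
#'
#' Drives the loop over a pose stream under the supplied clock: per frame,
#' displacement extraction (confidence-gated digit aggregation), causal
#' smoothing, the trial state machine, and — in `feedback` mode — a tone
#' command mapping the smoothed left-paw displacement to frequency. In
#' `control` mode the tone log stays empty but every other output is
#' identical. Stage delays (acquire, kinematics, fsm, tone; ms) may be
#' injected to exercise the latency instrumentation; under the simulated
#' clock the whole loop is exactly reproducible.
#'
#' @param stream a [pose_stream()].
#' @param cal a [calibration()].
#' @param cfg a [trial_config()].
#' @param soncfg a [sonification_config()].
#' @param mode `"feedback"` or `"control"`.
#' @param clock a clock; defaults to [simulated_clock()].
#' @param speed playback speed multiplier.
#' @param stage_delays named numeric (ms) with any of `acquire`,
#'   `kinematics`, `fsm`, `tone`; defaults to all 0.
#' @param meta list of session metadata (mouse, day, group, seed, ...).
#' @return An object of class `session_record`: `events` (session_start /
#'   led_on / FSM events / led_off / session_end), `kinematics` (raw and
#'   smoothed displacement per frame), `tones` (t, f_hz, active), `metrics`
#'   (per-frame delivery and stage-completion times), `config`, `mode`,
#'   `meta`.
#' @export
run_session <- function(stream, cal, cfg = trial_config(),
                        soncfg = sonification_config(),
                        mode = c("feedback", "control"),
                        clock = simulated_clock(), speed = 1,
                        stage_delays = NULL, meta = list()) {
  mode <- match.arg(mode)
  stopifnot(inherits(stream, "pose_stream"))
  n <- n_frames(stream)
  if (n == 0) stop("empty pose stream")
  delays <- c(acquire = 0, kinematics = 0, fsm = 0, tone = 0)
  if (!is.null(stage_delays)) {
    unknown <- setdiff(names(stage_delays), names(delays))
    if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
    delays[names(stage_delays)] <- stage_delays
  }
  delays_s <- delays / 1000

  t0 <- clock$now()
  t_deliver <- t0 + (stream$time - stream$time[1]) / speed
  clock$sleep_until(t_deliver[n])
  t_acq <- t_deliver + delays_s[["acquire"]]
  t_kin <- t_acq + delays_s[["kinematics"]]
  t_fsm <- t_kin + delays_s[["fsm"]]
  t_tone <- t_fsm + delays_s[["tone"]]

  kin <- stream_kinematics(stream, cal, cfg)
  kin <- smooth_kinematics(kin, cfg$smooth_window)

  fsm_events <- run_trial_fsm(t_deliver, kin$disp_left_smooth,
                              kin$valid_left, cfg,
                              event_t_offset = sum(delays_s[1:3]))

  tones <- if (mode == "feedback") {
    data.frame(t = t_tone,
               f_hz = map_frequency(kin$disp_left_smooth, soncfg),
               active = kin$valid_left & kin$disp_left_smooth > 0)
  } else {
    data.frame(t = numeric(0), f_hz = numeric(0), active = logical(0))
  }

  end_t <- max(t_deliver[n],
               if (nrow(fsm_events)) max(fsm_events$t) else -Inf)
  events <- rbind(
    data.frame(t = t0, kind = c("session_start", "led_on"),
               payload = NA_real_),
    fsm_events,
    data.frame(t = end_t, kind = c("led_off", "session_end"),
               payload = NA_real_))
  events <- events[order(events$t), , drop = FALSE]
  rownames(events) <- NULL

  metrics <- data.frame(
    frame = stream$frame, t_deliver = t_deliver,
    acquire_ms = rep(delays[["acquire"]], n),
    kinematics_ms = rep(delays[["kinematics"]], n),
    fsm_ms = rep(delays[["fsm"]], n),
    tone_ms = rep(delays[["tone"]], n),
    t_tone = t_tone)

  structure(list(events = events, kinematics = kin, tones = tones,
                 metrics = metrics,
                 config = list(trial = cfg, sonification = soncfg,
                               calibration = cal),
                 mode = mode, meta = meta),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  ns <- sum(x$events$kind == "success")
  cat(sprintf("<session_record> mode=%s, %d frames, %d events (%d successes), %d tone commands\n",
              x$mode, nrow(x$kinematics), nrow(x$events), ns, nrow(x$tones)))
  invisible(x)
}

#' Count successes in a session record
#' @param record a `session_record`.
#' @return integer number of success events.
#' @export
success_count <- function(record) sum(record$events$kind == "success")

#' Latency instrumentation summary
#'
#' Computes per-frame end-to-end latency (tone-command completion time
#' minus frame delivery time) and the loop rate from a session's metrics.
#' Under the simulated clock with injected stage delays the reported
#' latency equals the injected sum exactly.
#'
#' @param record a `session_record` with per-frame metrics.
#' @return An object of class `engine_metrics`: `latency_ms` (per frame),
#'   `mean_latency_ms`, `stage_means_ms`, `loop_rate_hz`.
#' @export
measure_latency <- function(record) {
  m <- record$metrics
  if (is.null(m) || !nrow(m) || is.null(m$t_tone) || is.null(m$t_deliver))
    stop("record carries no stage timestamps")
  # end-to-end latency is the per-frame sum of stage timings; under the
  # simulated clock this equals t_tone - t_deliver (checked in the tests)
  lat <- m$acquire_ms + m$kinematics_ms + m$fsm_ms + m$tone_ms
  dur <- m$t_deliver[nrow(m)] - m$t_deliver[1]
  structure(list(
    latency_ms = lat,
    mean_latency_ms = mean(lat),
    stage_means_ms = c(acquire = mean(m$acquire_ms),
                       kinematics = mean(m$kinematics_ms),
                       fsm = mean(m$fsm_ms), tone = mean(m$tone_ms)),
    loop_rate_hz = if (dur > 0) (nrow(m) - 1) / dur else NA_real_),
    class = "engine_metrics")
}

#' @export
print.engine_metrics <- function(x, ...) {
  cat(sprintf("<engine_metrics> mean end-to-end latency %.3f ms, loop rate %.2f Hz\n",
              x$mean_latency_ms, x$loop_rate_hz))
  invisible(x)
}

#' Check the event grammar of a session record
#'
#' Verifies the invariants every session must satisfy: events are
#' time-ordered; each `success` is immediately followed by exactly one
#' `reward` (and rewards appear nowhere else); reaches do not nest (no
#' second `reach_start` before the intervening `trial_reset`); the session
#' is bracketed by `session_start`/`session_end`.
#'
#' @param record a `session_record`.
#' @return `TRUE` if all invariants hold, otherwise a character vector of
#'   violations.
#' @export
validate_events <- function(record) {
  ev <- record$events
  bad <- character(0)
  if (is.unsorted(ev$t)) bad <- c(bad, "events not time-ordered")
  k <- ev$kind
  succ <- which(k == "success"); rew <- which(k == "reward")
  if (length(succ) != length(rew) || !all(rew == succ + 1))
    bad <- c(bad, "success/reward events not paired 1:1")
  core <- k[k %in% c("reach_start", "trial_reset")]
  if (length(core)) {
    r <- rle(core)
    if (any(r$lengths > 1)) bad <- c(bad, "nested or unmatched reaches")
  }
  if (k[1] != "session_start" || k[length(k)] != "session_end")
    bad <- c(bad, "session not bracketed by session_start/session_end")
  if (length(bad)) bad else TRUE
}
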
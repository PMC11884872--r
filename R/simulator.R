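#' Cohort design
#'
#' The study layout the simulator reproduces: two groups (auditory feedback
#' vs control) of `n_per_group` mice, trained one session per day for
#' `n_days` days, sessions of `session_length` seconds captured at `fps`.
#' Defaults follow the 7-vs-7 mouse, 4-day, 30-minute design at ~70 fps.
#'
#' @param n_per_group mice per group.
#' @param n_days training days.
#' @param session_length session duration (s).
#' @param fps camera frame rate (Hz).
#' @param groups group labels; the first label receives auditory feedback.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = 7, n_days = 4, session_length = 1800,
                          fps = 70, groups = c("feedback", "control")) {
  stopifnot(n_per_group >= 1, n_days >= 1, session_length > 0, fps > 0,
            length(groups) == 2)
  structure(list(n_per_group = as.integer(n_per_group),
                 n_days = as.integer(n_days),
                 session_length = session_length, fps = fps,
                 groups = as.character(groups)),
            class = "cohort_design")
}

#' Learning-dynamics parameters for the simulator
#'
#' Parameterizes the planted motor-learning phenomenon: left-paw reach rate
#' grows multiplicatively per day (faster in the feedback group), reach
#' apexes are drawn from a normal distribution whose spread shrinks per day
#' in the feedback group (trajectories become more consistent), and the
#' right paw reaches at a constant rate, providing the denominator of the
#' reach ratio. All values are stand-ins chosen to be realistic for
#' head-fixed mouse reaching; no distributional parameters are reported for
#' the real animals.
#'
#' @param base_reach_rate Day-1 left-paw reach rate (reaches/min).
#' @param rate_gain_feedback,rate_gain_control multiplicative per-day rate
#'   gains; feedback >= control under defaults.
#' @param peak_mean mean reach apex (mm); slightly above the 15 mm target
#'   so that both successful and failed reaches occur.
#' @param peak_sd Day-1 apex SD (mm).
#' @param peak_sd_gain_feedback,peak_sd_gain_control multiplicative per-day
#'   gains on the apex SD (< 1 means growing consistency).
#' @param noise_sd additive kinematic jitter (mm) on each paw's
#'   displacement trace.
#' @param right_paw_rate right-paw reach rate (reaches/min), constant
#'   across days.
#' @param right_peak_mean,right_peak_sd right-paw apex distribution (mm).
#' @param reach_duration,duration_sd reach duration mean and SD (s).
#' @param min_gap minimum rest interval between consecutive reaches of one
#'   paw (s); kept above the trial refractory so every planted reach is a
#'   countable attempt.
#' @param dropout_rate per digit-frame probability that tracking confidence
#'   collapses (likelihood 0.2, below the default gating floor).
#' @return An object of class `learning_params`.
#' @export
learning_params <- function(base_reach_rate = 2, rate_gain_feedback = 1.35,
                            rate_gain_control = 1.10, peak_mean = 16,
                            peak_sd = 3, peak_sd_gain_feedback = 0.8,
                            peak_sd_gain_control = 1.0, noise_sd = 0.3,
                            right_paw_rate = 2, right_peak_mean = 10,
                            right_peak_sd = 2, reach_duration = 0.8,
                            duration_sd = 0.1, min_gap = 1.0,
                            dropout_rate = 0.01) {
  p <- list(base_reach_rate = base_reach_rate,
            rate_gain_feedback = rate_gain_feedback,
            rate_gain_control = rate_gain_control,
            peak_mean = peak_mean, peak_sd = peak_sd,
            peak_sd_gain_feedback = peak_sd_gain_feedback,
            peak_sd_gain_control = peak_sd_gain_control,
            noise_sd = noise_sd, right_paw_rate = right_paw_rate,
            right_peak_mean = right_peak_mean, right_peak_sd = right_peak_sd,
            reach_duration = reach_duration, duration_sd = duration_sd,
            min_gap = min_gap, dropout_rate = dropout_rate)
  rates <- c(p$base_reach_rate, p$right_paw_rate)
  if (any(rates < 0)) stop("reach rates must be >= 0")
  if (any(c(p$peak_sd, p$noise_sd, p$duration_sd) < 0))
    stop("standard deviations must be >= 0")
  if (p$rate_gain_feedback < p$rate_gain_control)
    stop("rate_gain_feedback must be >= rate_gain_control")
  if (p$dropout_rate < 0 || p$dropout_rate > 1)
    stop("dropout_rate must be in [0, 1]")
  structure(p, class = "learning_params")
}

#' Simulate one reach displacement segment
#'
#' A smooth bell-shaped vertical displacement profile: the minimum-jerk
#' position profile (10u^3 - 15u^4 + 6u^5) rises to the apex over the first
#' half of the reach and mirrors back down, then is rescaled so the sampled
#' maximum equals `apex` exactly; optional additive jitter on top. Starts
#' and ends at 0 (within the noise).
#'
#' @param apex peak displacement (mm), > 0.
#' @param duration reach duration (s), > 0.
#' @param fps sampling rate (Hz).
#' @param noise_sd additive Gaussian jitter SD (mm).
#' @return Numeric vector of `round(duration * fps)` displacement samples (mm).
#' @export
simulate_reach <- function(apex, duration, fps = 70, noise_sd = 0) {
  if (!is.numeric(apex) || apex <= 0) stop("apex must be > 0")
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  n <- max(3L, as.integer(round(duration * fps)))
  tau <- seq(0, 1, length.out = n)
  mj <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5
  prof <- ifelse(tau <= 0.5, mj(2 * tau), mj(2 * (1 - tau)))
  prof <- prof / max(prof) * apex
  if (noise_sd > 0) prof <- prof + rnorm(n, 0, noise_sd)
  prof
}

# Draw a reach schedule for one paw: Poisson onsets thinned to enforce a
# minimum rest gap between consecutive reaches.
plan_reaches <- function(rate_per_min, session_length, apex_mean, apex_sd,
                         duration_mean, duration_sd, min_gap) {
  empty <- data.frame(onset = numeric(0), duration = numeric(0),
                      apex = numeric(0))
  if (rate_per_min <= 0) return(empty)
  mean_gap <- 60 / rate_per_min
  onsets <- numeric(0)
  t <- rexp(1, 1 / mean_gap)
  prev_end <- -Inf
  while (t < session_length - 2 * duration_mean) {
    dur <- max(0.3, rnorm(1, duration_mean, duration_sd))
    if (t >= prev_end + min_gap) {
      onsets <- c(onsets, t)
      prev_end <- t + dur
      if (length(onsets) == 1) durations <- dur else durations <- c(durations, dur)
    }
    t <- t + rexp(1, 1 / mean_gap)
  }
  if (!length(onsets)) return(empty)
  apex <- pmax(0.5, rnorm(length(onsets), apex_mean, apex_sd))
  data.frame(onset = onsets, duration = durations, apex = apex)
}

# Per-day effective parameters for one group.
day_params <- function(params, day, group, design) {
  fb <- group == design$groups[1]
  gain <- if (fb) params$rate_gain_feedback else params$rate_gain_control
  sd_gain <- if (fb) params$peak_sd_gain_feedback else params$peak_sd_gain_control
  list(rate = params$base_reach_rate * gain^(day - 1),
       apex_sd = params$peak_sd * sd_gain^(day - 1))
}

#' Simulate one training session
#'
#' Generates the forepaw pose stream and ground truth for one mouse on one
#' day. Left-paw reaches are planted at a Poisson rate that grows with
#' training (faster in the feedback group), with minimum-jerk kinematics
#' and apexes drawn around the target height; right-paw reaches occur at a
#' constant rate. Displacement is converted to pixel-space keypoints (four
#' digits per paw, y down) through an internal [calibration()], so the full
#' pixel-to-mm code path is exercised downstream.
#'
#' @param mouse mouse identifier.
#' @param day training day, in `1:design$n_days`.
#' @param group group label, one of `design$groups`.
#' @param params a [learning_params()].
#' @param design a [cohort_design()].
#' @param seed integer seed; fixed seed gives an identical session.
#' @param target_offset target-zone height (mm) used for the ground-truth
#'   success flag (apex >= target_offset).
#' @return A list of class `sim_session`: `stream` (a [pose_stream()]),
#'   `truth` (data frame of planted reaches: paw, onset, duration, apex,
#'   success), `counts` (planted reaches per paw), `calibration`, and the
#'   session metadata.
#' @export
simulate_session <- function(mouse, day, group, params = learning_params(),
                             design = cohort_design(), seed = 1,
                             target_offset = 15) {
  stopifnot(day >= 1, day <= design$n_days)
  if (!group %in% design$groups)
    stop("unknown group '", group, "'")
  set.seed(seed)
  fps <- design$fps
  n <- as.integer(round(design$session_length * fps))
  tm <- (seq_len(n) - 1L) / fps

  dp <- day_params(params, day, group, design)
  left <- plan_reaches(dp$rate, design$session_length, params$peak_mean,
                       dp$apex_sd, params$reach_duration, params$duration_sd,
                       params$min_gap)
  right <- plan_reaches(params$right_paw_rate, design$session_length,
                        params$right_peak_mean, params$right_peak_sd,
                        params$reach_duration, params$duration_sd,
                        params$min_gap)

  place <- function(plan) {
    disp <- numeric(n)
    for (k in seq_len(nrow(plan))) {
      seg <- simulate_reach(plan$apex[k], plan$duration[k], fps)
      i0 <- as.integer(round(plan$onset[k] * fps)) + 1L
      if (i0 > n) next
      idx <- i0:min(n, i0 + length(seg) - 1L)
      disp[idx] <- disp[idx] + seg[seq_along(idx)]
    }
    disp
  }
  disp_left <- place(left)
  disp_right <- place(right)
  if (params$noise_sd > 0) {
    disp_left <- disp_left + rnorm(n, 0, params$noise_sd)
    disp_right <- disp_right + rnorm(n, 0, params$noise_sd)
  }

  cal <- calibration(mm_per_pixel = 0.1, rest_y_left = 300,
                     rest_y_right = 300)
  digit_offsets <- c(-6, -2, 2, 6)   # px, symmetric so the centroid is rest_y
  bodyparts <- c(paste0("left_digit", 1:4), paste0("right_digit", 1:4))
  y <- cbind(
    outer(cal$rest_y_left - disp_left / cal$mm_per_pixel, digit_offsets, `+`),
    outer(cal$rest_y_right - disp_right / cal$mm_per_pixel, digit_offsets, `+`))
  x <- cbind(matrix(rep(200 + digit_offsets, each = n), n, 4),
             matrix(rep(440 + digit_offsets, each = n), n, 4))
  lik <- matrix(0.99, n, 8)
  if (params$dropout_rate > 0) {
    drop <- matrix(runif(n * 8) < params$dropout_rate, n, 8)
    lik[drop] <- 0.2
  }
  stream <- pose_stream(x, y, lik, bodyparts = bodyparts, fps = fps)

  truth <- rbind(
    if (nrow(left)) cbind(paw = "left", left) else NULL,
    if (nrow(right)) cbind(paw = "right", right) else NULL)
  if (is.null(truth))
    truth <- data.frame(paw = character(0), onset = numeric(0),
                        duration = numeric(0), apex = numeric(0))
  truth$success <- truth$apex >= target_offset & truth$paw == "left"
  truth <- truth[order(truth$onset), , drop = FALSE]
  rownames(truth) <- NULL

  structure(list(stream = stream, truth = truth,
                 counts = c(left = nrow(left), right = nrow(right)),
                 calibration = cal, mouse = mouse, day = day, group = group,
                 seed = seed), class = "sim_session")
}

# Deterministic per-session seed table derived from one master seed.
cohort_session_table <- function(design, seed) {
  mice <- c(paste0("f", seq_len(design$n_per_group)),
            paste0("c", seq_len(design$n_per_group)))
  groups <- rep(design$groups, each = design$n_per_group)
  tab <- expand.grid(day = seq_len(design$n_days),
                     idx = seq_along(mice), KEEP.OUT.ATTRS = FALSE)
  tab <- data.frame(mouse = mice[tab$idx], group = groups[tab$idx],
                    day = tab$day, stringsAsFactors = FALSE)
  set.seed(seed)
  tab$seed <- sample.int(.Machine$integer.max - 1L, nrow(tab))
  tab[order(tab$mouse, tab$day), ]
}

#' Simulate a full cohort
#'
#' Runs [simulate_session()] for every mouse x day cell of the design
#' (`n_per_group` x 2 groups x `n_days` sessions); per-session seeds are
#' derived deterministically from the master seed, so the whole cohort is
#' reproducible and any single session can be regenerated independently.
#'
#' @inheritParams simulate_session
#' @param design a [cohort_design()].
#' @param seed master seed.
#' @param out_dir if non-`NULL`, each session's pose stream is written as a
#'   pose CSV and its ground truth as JSON lines under `out_dir`, and only
#'   the manifest is returned (keeps memory flat for long sessions).
#' @return A list with `manifest` (data frame: mouse, group, day, seed and,
#'   with `out_dir`, file paths) and — without `out_dir` — `sessions`, the
#'   list of `sim_session` objects.
#' @export
simulate_cohort <- function(design = cohort_design(),
                            params = learning_params(), seed = 1,
                            out_dir = NULL, target_offset = 15) {
  tab <- cohort_session_table(design, seed)
  sessions <- if (is.null(out_dir)) vector("list", nrow(tab)) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tab$pose_csv <- tab$truth_jsonl <- NA_character_
  }
  for (i in seq_len(nrow(tab))) {
    ses <- simulate_session(tab$mouse[i], tab$day[i], tab$group[i], params,
                            design, seed = tab$seed[i],
                            target_offset = target_offset)
    if (is.null(out_dir)) {
      sessions[[i]] <- ses
    } else {
      stem <- file.path(out_dir, sprintf("%s_day%d", tab$mouse[i], tab$day[i]))
      write_pose_csv(ses$stream, paste0(stem, "_pose.csv"))
      writeLines(vapply(seq_len(nrow(ses$truth)), function(k)
        jsonlite::toJSON(as.list(ses$truth[k, ]), auto_unbox = TRUE),
        character(1)), paste0(stem, "_truth.jsonl"))
      tab$pose_csv[i] <- paste0(stem, "_pose.csv")
      tab$truth_jsonl[i] <- paste0(stem, "_truth.jsonl")
    }
  }
  rownames(tab) <- NULL
  list(manifest = tab, sessions = sessions, design = design, params = params,
       seed = seed)
}
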
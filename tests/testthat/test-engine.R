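test_that("displacement extraction gates on likelihood and holds last value", {
  cal <- default_cal()
  cfg <- trial_config()
  s <- disp_to_stream(c(0, 15, 8))
  kin <- stream_kinematics(s, cal, cfg)
  expect_equal(kin$disp_left, c(0, 15, 8))
  expect_equal(kin$disp_right, c(0, 0, 0))
  expect_true(all(kin$valid_left))

  # all left digits below the confidence floor: invalid, hold-last
  s2 <- disp_to_stream(c(0, 15, 8))
  s2$likelihood[3, 1:4] <- 0.2
  kin2 <- stream_kinematics(s2, cal, cfg)
  expect_false(kin2$valid_left[3])
  expect_equal(kin2$disp_left[3], 15)   # previous sample's value
  expect_true(kin2$valid_right[3])

  # per-frame variant agrees
  prev <- compute_displacement(get_frame(s2, 2), cal, cfg)
  cur <- compute_displacement(get_frame(s2, 3), cal, cfg, prev = prev)
  expect_false(cur$valid_left)
  expect_equal(cur$disp_left, prev$disp_left)
  expect_error(compute_displacement(get_frame(s2, 1), NULL, cfg),
               "calibration")
})

test_that("causal smoothing matches hand-computed moving averages", {
  expect_equal(smooth_causal(c(3, 1, 4, 1, 5), 1), c(3, 1, 4, 1, 5))
  expect_equal(smooth_causal(rep(7, 10), 4), rep(7, 10))
  step <- c(0, 0, 0, 10, 10, 10)
  expect_equal(smooth_causal(step, 3), c(0, 0, 0, 10 / 3, 20 / 3, 10))
  expect_error(smooth_causal(1:5, 0), "window")
})

test_that("the trial machine reproduces a hand-traced event list", {
  cfg <- trial_config()  # target 15, tolerance 2, refractory 0.5
  disp <- c(0, 1, 5, 10, 16, 18, 10, 3, 1, 0)   # full reach and return
  t <- (seq_along(disp) - 1) / 10                # 0.1 s per sample
  ev <- reachtone:::run_trial_fsm(t, disp, rep(TRUE, 10), cfg)
  expect_equal(ev$kind, c("reach_start", "target_entry", "success",
                          "reward", "trial_reset"))
  expect_equal(ev$t, c(0.2, 0.4, 0.4, 0.4, 0.9))
  # reward carries the 5 ul volume; reset waited for refractory + return
  expect_equal(ev$payload[ev$kind == "reward"], 5)
  expect_true(ev$t[5] >= 0.4 + cfg$refractory)

  # sub-threshold attempt: only reach_start and trial_reset
  disp2 <- c(0, 3, 8, 10, 9, 4, 1, 0)
  ev2 <- reachtone:::run_trial_fsm((seq_along(disp2) - 1) / 10, disp2,
                                   rep(TRUE, 8), cfg)
  expect_equal(ev2$kind, c("reach_start", "trial_reset"))

  # two full ramps closer than the refractory: only one success
  ramp <- c(0, 8, 16, 8, 0)
  disp3 <- c(ramp, ramp, rep(0, 3))
  t3 <- (seq_along(disp3) - 1) / 70              # whole ramp pair < 0.5 s
  ev3 <- reachtone:::run_trial_fsm(t3, disp3, rep(TRUE, length(disp3)), cfg)
  expect_equal(sum(ev3$kind == "success"), 1)
})

test_that("state stepping API agrees with the batch run", {
  cfg <- trial_config()
  disp <- c(0, 5, 16, 5, 0, 0, 0, 0, 5, 16, 1, 0)
  t <- (seq_along(disp) - 1) / 10
  st <- fsm_state()
  evs <- NULL
  for (i in seq_along(disp)) {
    out <- step_trial_fsm(st, list(t = t[i], disp_left = disp[i],
                                   valid_left = TRUE), cfg)
    st <- out$state
    evs <- rbind(evs, out$events)
  }
  batch <- reachtone:::run_trial_fsm(t, disp, rep(TRUE, length(disp)), cfg)
  expect_equal(evs$kind, batch$kind)
  expect_equal(evs$t, batch$t)
  expect_equal(st$n_success, sum(batch$kind == "success"))
})

test_that("invalid samples freeze the state machine", {
  cfg <- trial_config()
  disp <- c(0, 5, 16, 5, 0)
  valid <- c(TRUE, TRUE, FALSE, TRUE, TRUE)   # the crossing frame is invalid
  ev <- reachtone:::run_trial_fsm((0:4) / 10, disp, valid, cfg)
  expect_equal(sum(ev$kind == "success"), 0)
  expect_equal(ev$kind, c("reach_start", "trial_reset"))
})

test_that("engine success counts match the brute-force excursion oracle", {
  cfg <- trial_config()
  for (seed in 1:200) {
    seqv <- random_fsm_sequence(seed)
    ev <- reachtone:::run_trial_fsm(seqv$t, seqv$disp, seqv$valid, cfg)
    oracle <- oracle_reach_counts(seqv$t, seqv$disp, seqv$valid, cfg)
    expect_equal(sum(ev$kind == "success"), unname(oracle["successes"]),
                 info = paste("seed", seed))
    expect_equal(sum(ev$kind == "reach_start"), unname(oracle["attempts"]),
                 info = paste("seed", seed))
  }
})

test_that("control mode differs from feedback only in the tone log", {
  ses <- simulate_session("m", 1, "feedback",
                          learning_params(noise_sd = 0, dropout_rate = 0),
                          cohort_design(session_length = 20), seed = 4)
  fb <- run_session(ses$stream, ses$calibration, mode = "feedback")
  ctl <- run_session(ses$stream, ses$calibration, mode = "control")
  expect_gt(nrow(fb$tones), 0)
  expect_equal(nrow(ctl$tones), 0)
  expect_identical(ctl$events, fb$events)
  expect_identical(ctl$kinematics, fb$kinematics)
  expect_identical(ctl$metrics, fb$metrics)

  fb2 <- run_session(ses$stream, ses$calibration, mode = "feedback")
  expect_identical(fb2$events, fb$events)
  expect_identical(fb2$tones, fb$tones)
})

test_that("sessions end cleanly and satisfy the event grammar", {
  ses <- simulate_session("m", 2, "control", learning_params(),
                          cohort_design(session_length = 30), seed = 8)
  rec <- run_session(ses$stream, ses$calibration, mode = "control")
  expect_true(isTRUE(validate_events(rec)))
  k <- rec$events$kind
  expect_equal(k[1], "session_start")
  expect_equal(k[length(k)], "session_end")
})

test_that("latency instrumentation reports injected stage delays exactly", {
  ses <- simulate_session("m", 1, "feedback",
                          learning_params(noise_sd = 0, dropout_rate = 0),
                          cohort_design(session_length = 5), seed = 1)
  rec <- run_session(ses$stream, ses$calibration,
                     stage_delays = c(acquire = 5, kinematics = 10, fsm = 15))
  m <- measure_latency(rec)
  expect_equal(unique(m$latency_ms), 30)
  expect_equal(m$mean_latency_ms, 30)

  rec0 <- run_session(ses$stream, ses$calibration)
  expect_equal(measure_latency(rec0)$mean_latency_ms, 0)
  expect_equal(measure_latency(rec0)$loop_rate_hz, 70, tolerance = 1e-6)

  set.seed(3)
  d <- runif(4, 0, 20)
  rec_r <- run_session(ses$stream, ses$calibration,
                       stage_delays = c(acquire = d[1], kinematics = d[2],
                                        fsm = d[3], tone = d[4]))
  mr <- measure_latency(rec_r)
  expect_equal(mr$mean_latency_ms, sum(d), tolerance = 1e-12)
  # stage-sum bookkeeping agrees with the timestamp difference
  ts_lat <- (rec_r$metrics$t_tone - rec_r$metrics$t_deliver) * 1000
  expect_equal(ts_lat, mr$latency_ms, tolerance = 1e-9)

  rec_bad <- rec0
  rec_bad$metrics <- NULL
  expect_error(measure_latency(rec_bad), "timestamps")
  expect_error(run_session(ses$stream, ses$calibration,
                           stage_delays = c(gpu = 1)), "unknown stage")
})
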
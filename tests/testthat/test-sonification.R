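test_that("the displacement-to-frequency map is linear with clipped endpoints", {
  cfg <- sonification_config()
  expect_equal(map_frequency(0, cfg), 2000)
  expect_equal(map_frequency(15, cfg), 20000)
  expect_equal(map_frequency(7.5, cfg), 11000)
  expect_equal(map_frequency(-3, cfg), 2000)    # clipped below
  expect_equal(map_frequency(40, cfg), 20000)   # clipped above

  # monotone non-decreasing and exactly linear inside [0, d_max]
  d <- seq(-5, 25, by = 0.1)
  f <- map_frequency(d, cfg)
  expect_true(all(diff(f) >= 0))
  inside <- d >= 0 & d <= 15
  expect_equal(f[inside], 2000 + (20000 - 2000) * d[inside] / 15)
})

test_that("synthesis produces the commanded tone and handles empty input", {
  cfg <- sonification_config(f_min = 500, f_max = 2000, sample_rate = 44100)
  cmd <- data.frame(t = 0, f_hz = 1000, active = TRUE)
  w <- synthesize(cmd, cfg, duration = 1)
  expect_length(w$samples, 44100)
  pk <- spectrogram_peak_track(w, n_window = 4096)
  expect_true(all(abs(pk$peak_hz - 1000) <= 44100 / 4096, na.rm = TRUE))

  w0 <- synthesize(data.frame(t = numeric(0), f_hz = numeric(0),
                              active = logical(0)), cfg, duration = 0.5)
  expect_equal(w0$samples, numeric(0.5 * 44100))

  expect_error(synthesize(cmd, sonification_config(sample_rate = 30000)),
               "aliasing")
})

test_that("frequency steps keep phase continuity (no clicks)", {
  cfg <- sonification_config(f_min = 500, f_max = 2000, amplitude = 0.8,
                             ramp_ms = 0)
  cmds <- data.frame(t = c(0, 0.25, 0.5, 0.75),
                     f_hz = c(1000, 2000, 800, 1700),
                     active = TRUE)
  w <- synthesize(cmds, cfg, duration = 1)
  # a continuous-phase sine's sample-to-sample jump is bounded by
  # 2 sin(pi f / sr); a phase jump could approach 2 * amplitude
  bound <- 2 * sin(pi * 2000 / cfg$sample_rate) * cfg$amplitude
  expect_lte(max(abs(diff(w$samples))), bound + 1e-9)
})

test_that("spectral peak tracking follows pure tones and chirps", {
  sr <- 44100
  ts <- (0:(sr - 1)) / sr
  pure <- list(samples = sin(2 * pi * 5000 * ts), sample_rate = sr)
  trk <- spectrogram_peak_track(pure, n_window = 2048)
  expect_true(all(abs(trk$peak_hz - 5000) <= sr / 2048))

  f0 <- 2000; f1 <- 20000
  chirp <- list(samples = sin(2 * pi * (f0 * ts + (f1 - f0) / 2 * ts^2)),
                sample_rate = sr)
  trk2 <- spectrogram_peak_track(chirp, n_window = 1024)
  expect_true(all(diff(trk2$peak_hz) >= 0, na.rm = TRUE))

  expect_error(spectrogram_peak_track(list(samples = numeric(0),
                                           sample_rate = sr)), "empty")
})

test_that("session audio closes the loop against the tone log", {
  ses <- simulate_session("m", 1, "feedback",
                          learning_params(noise_sd = 0, dropout_rate = 0),
                          cohort_design(session_length = 30), seed = 6)
  rec <- run_session(ses$stream, ses$calibration)
  va <- validate_session_audio(rec)
  expect_gte(va$frac_within_one_bin, 0.99)
  expect_gt(va$n_windows, 10)
})

test_that("frequency-displacement correlation is exact without noise and degrades with jitter", {
  ses <- simulate_session("m", 1, "feedback",
                          learning_params(noise_sd = 0, dropout_rate = 0),
                          cohort_design(session_length = 60), seed = 6)
  rec <- run_session(ses$stream, ses$calibration)
  res <- frequency_displacement_correlation(rec)
  expect_equal(res$pearson_r, 1.0, tolerance = 1e-12)
  # slope of the linear map: (20000 - 2000) Hz / 15 mm
  expect_equal(res$slope, 1200, tolerance = 1e-9)

  set.seed(2)
  rs <- vapply(c(0.5, 2), function(noise) {
    rj <- rec
    rj$kinematics$disp_left_smooth <-
      rj$kinematics$disp_left_smooth + rnorm(nrow(rj$kinematics), 0, noise)
    frequency_displacement_correlation(rj)$pearson_r
  }, numeric(1))
  expect_true(all(rs < 1))
  expect_lt(rs[2], rs[1])  # more jitter, weaker correlation

  ctl <- run_session(ses$stream, ses$calibration, mode = "control")
  expect_error(frequency_displacement_correlation(ctl), "no tone commands")
})

test_that("waveforms serialize to valid 16-bit PCM WAV", {
  w <- synthesize(data.frame(t = 0, f_hz = 3000, active = TRUE),
                  sonification_config(), duration = 0.1)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, path)
  expect_equal(file.size(path), 44 + 2 * length(w$samples))
  con <- file(path, "rb")
  magic <- readChar(con, 4)
  close(con)
  expect_equal(magic, "RIFF")
})
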
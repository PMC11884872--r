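#' Sonification configuration
#'
#' The displacement-to-frequency map and synthesis parameters. Tone
#' frequency spans `f_min`..`f_max` (defaults 2 and 20 kHz, the band a
#' standard speaker reproduces reliably and in which mice retain good
#' audible sensitivity); displacement is mapped linearly over
#' `[0, d_max]` mm and clipped outside, so `d_max` (default 15 mm, the
#' target height) corresponds to `f_max`.
#'
#' @param f_min,f_max frequency endpoints (Hz), `0 < f_min < f_max`.
#' @param d_max displacement mapped to `f_max` (mm), > 0.
#' @param amplitude peak amplitude in `(0, 1]`.
#' @param sample_rate synthesis rate (Hz); must exceed `2 * f_max`.
#' @param ramp_ms raised-cosine on/off amplitude ramp (ms).
#' @return An object of class `sonification_config`.
#' @export
sonification_config <- function(f_min = 2000, f_max = 20000, d_max = 15,
                                amplitude = 0.8, sample_rate = 44100,
                                ramp_ms = 5) {
  if (!(f_min > 0 && f_max > f_min)) stop("need 0 < f_min < f_max")
  if (d_max <= 0) stop("d_max must be > 0")
  if (amplitude <= 0 || amplitude > 1) stop("amplitude must be in (0, 1]")
  if (ramp_ms < 0) stop("ramp_ms must be >= 0")
  structure(list(f_min = f_min, f_max = f_max, d_max = d_max,
                 amplitude = amplitude, sample_rate = sample_rate,
                 ramp_ms = ramp_ms), class = "sonification_config")
}

#' Map displacement to tone frequency
#'
#' The linear movement-coding map: `f = f_min + (f_max - f_min) *
#' clip(disp / d_max, 0, 1)`. Displacement at or below rest gives `f_min`;
#' at or above `d_max` gives `f_max`.
#'
#' @param disp displacement (mm), vectorized.
#' @param cfg a [sonification_config()].
#' @return Frequency in Hz, same length as `disp`.
#' @export
map_frequency <- function(disp, cfg = sonification_config()) {
  frac <- pmin(pmax(disp / cfg$d_max, 0), 1)
  cfg$f_min + (cfg$f_max - cfg$f_min) * frac
}

#' Synthesize tone-command audio
#'
#' Renders a time-ordered tone-command log into a waveform: a piecewise
#' sine with zero-order-hold frequency between commands and a running
#' phase accumulator, so frequency steps introduce no phase discontinuity;
#' raised-cosine amplitude ramps of `ramp_ms` smooth every on/off
#' transition; inactive spans are silence.
#'
#' @param commands data frame with `t` (s), `f_hz`, `active`; time-ordered.
#' @param cfg a [sonification_config()].
#' @param duration total duration (s); defaults to the command span plus
#'   one median command interval.
#' @return An object of class `audio_wave`: `samples` in `[-1, 1]` and
#'   `sample_rate`.
#' @export
synthesize <- function(commands, cfg = sonification_config(),
                       duration = NULL) {
  sr <- cfg$sample_rate
  if (sr < 2 * cfg$f_max)
    stop("sample_rate must be at least 2 * f_max (aliasing)")
  if (is.null(commands) || !nrow(commands)) {
    n <- if (is.null(duration)) 0L else as.integer(round(duration * sr))
    return(structure(list(samples = numeric(n), sample_rate = sr),
                     class = "audio_wave"))
  }
  if (is.unsorted(commands$t)) stop("commands must be time-ordered")
  t_rel <- commands$t - commands$t[1]
  if (is.null(duration)) {
    step <- if (nrow(commands) > 1) median(diff(t_rel)) else 1 / 70
    duration <- t_rel[length(t_rel)] + step
  }
  n <- as.integer(round(duration * sr))
  ts <- (seq_len(n) - 1L) / sr
  idx <- findInterval(ts, t_rel)           # 0 before the first command
  f <- ifelse(idx >= 1, commands$f_hz[pmax(idx, 1L)], 0)
  f[!is.finite(f)] <- 0
  on <- idx >= 1 & commands$active[pmax(idx, 1L)]
  phase <- cumsum(2 * pi * f / sr)

  env <- cfg$amplitude * as.numeric(on)
  r <- as.integer(round(cfg$ramp_ms / 1000 * sr))
  if (r > 1) {
    ramp <- (1 - cos(pi * seq_len(r) / r)) / 2   # 0 -> 1 raised cosine
    flips <- which(diff(as.numeric(on)) != 0)
    for (k in flips) {
      if (on[k + 1]) {                            # turning on at k+1
        span <- (k + 1):min(n, k + r)
        env[span] <- env[span] * ramp[seq_along(span)]
      } else {                                    # turning off after k
        span <- max(1, k - r + 1):k
        env[span] <- env[span] * rev(ramp)[seq_along(span) +
                                             (r - length(span))]
      }
    }
  }
  structure(list(samples = env * sin(phase), sample_rate = sr),
            class = "audio_wave")
}

#' @export
print.audio_wave <- function(x, ...) {
  cat(sprintf("<audio_wave> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Short-time spectral peak tracking
#'
#' Slides a rectangular window over the waveform and reports the frequency
#' of the magnitude-spectrum peak per window (silent windows give `NA`).
#' The frequency resolution — one bin — is `sample_rate / n_window`.
#'
#' @param wave an `audio_wave` from [synthesize()] (or a list with
#'   `samples` and `sample_rate`).
#' @param n_window window length (samples).
#' @param hop hop between windows (samples); defaults to `n_window`.
#' @param silence_rms RMS threshold below which a window is silent.
#' @return Data frame: `t_center` (s), `peak_hz` (`NA` when silent),
#'   `rms`.
#' @export
spectrogram_peak_track <- function(wave, n_window = 1024, hop = n_window,
                                   silence_rms = 1e-4) {
  s <- wave$samples; sr <- wave$sample_rate
  if (!length(s)) stop("empty waveform")
  starts <- seq(1, max(1, length(s) - n_window + 1), by = hop)
  nyq <- floor(n_window / 2)
  out <- vapply(starts, function(i) {
    w <- s[i:min(length(s), i + n_window - 1)]
    rms <- sqrt(mean(w^2))
    if (rms < silence_rms) return(c(NA_real_, rms))
    mag <- Mod(fft(c(w, numeric(n_window - length(w)))))[2:(nyq + 1)]
    c(which.max(mag) * sr / n_window, rms)
  }, numeric(2))
  data.frame(t_center = (starts - 1 + n_window / 2) / sr,
             peak_hz = out[1, ], rms = out[2, ])
}

#' Validate synthesized session audio against the tone log
#'
#' Closes the synthesis-analysis loop: the session audio is cut at the
#' tone-command boundaries (frequency is constant within each command's
#' hold interval), each active interval's spectral peak is measured by
#' FFT, and compared with the commanded frequency. The tolerance is one
#' frequency bin of that interval's FFT (`sample_rate / n_samples`).
#'
#' @param record a `session_record` from a feedback-mode [run_session()].
#' @param wave optional pre-rendered `audio_wave`; synthesized from the
#'   record's tone log when `NULL`.
#' @param min_samples active intervals shorter than this many samples are
#'   skipped (too short to carry a measurable spectrum).
#' @return A list: `frac_within_one_bin`, `n_windows`, `details` (per
#'   window: commanded and recovered frequency, bin width, match flag).
#' @export
validate_session_audio <- function(record, wave = NULL, min_samples = 32) {
  cmds <- record$tones
  if (is.null(cmds) || !nrow(cmds)) stop("no tone commands in record")
  cfg <- record$config$sonification
  if (is.null(wave)) wave <- synthesize(cmds, cfg)
  sr <- wave$sample_rate
  t_rel <- cmds$t - cmds$t[1]
  step <- if (nrow(cmds) > 1) median(diff(t_rel)) else 1 / 70
  bounds <- c(t_rel, t_rel[length(t_rel)] + step)
  res <- lapply(which(cmds$active), function(k) {
    i0 <- as.integer(round(bounds[k] * sr)) + 1L
    i1 <- min(length(wave$samples), as.integer(round(bounds[k + 1] * sr)))
    if (i1 - i0 + 1 < min_samples) return(NULL)
    w <- wave$samples[i0:i1]
    nw <- length(w)
    nyq <- floor(nw / 2)
    mag <- Mod(fft(w))[2:(nyq + 1)]
    peak <- which.max(mag) * sr / nw
    data.frame(t = cmds$t[k], f_commanded = cmds$f_hz[k], f_recovered = peak,
               bin_hz = sr / nw)
  })
  details <- do.call(rbind, res)
  if (is.null(details) || !nrow(details))
    stop("no active tone intervals long enough to analyze")
  details$within_one_bin <-
    abs(details$f_recovered - details$f_commanded) <= details$bin_hz
  list(frac_within_one_bin = mean(details$within_one_bin),
       n_windows = nrow(details), details = details)
}

#' Correlation between tone frequency and paw displacement
#'
#' Pairs each active tone command with the concurrent smoothed left-paw
#' displacement sample (nearest timestamp within one frame period) and,
#' on the within-range pairs (0 < disp < `d_max`, where the map is not
#' clipped), returns the Pearson correlation and the ordinary
#' least-squares slope with a 95% confidence interval.
#'
#' @param record a `session_record` with tone log and kinematics.
#' @return An object of class `correlation_result`: `pearson_r`, `slope`
#'   (Hz/mm), `slope_ci`, `intercept`, `n`.
#' @export
frequency_displacement_correlation <- function(record) {
  tones <- record$tones
  if (is.null(tones) || !nrow(tones)) stop("no tone commands")
  kin <- record$kinematics
  act <- tones[tones$active, , drop = FALSE]
  if (!nrow(act)) stop("no active tone commands")
  kt <- record$metrics$t_deliver %||% kin$t
  frame_period <- if (length(kt) > 1) median(diff(kt)) else Inf
  idx <- vapply(act$t, function(tt) which.min(abs(kt - tt)), integer(1))
  ok <- abs(kt[idx] - act$t) <= frame_period
  disp <- kin$disp_left_smooth[idx][ok]
  f <- act$f_hz[ok]
  cfg <- record$config$sonification
  inr <- disp > 0 & disp < cfg$d_max
  disp <- disp[inr]; f <- f[inr]
  if (length(f) < 3) stop("fewer than 3 unclipped tone/displacement pairs")
  fit <- lm(f ~ disp)
  # confint on an exactly collinear (noise-free) fit warns harmlessly
  ci <- suppressWarnings(stats::confint(fit)["disp", ])
  structure(list(pearson_r = cor(disp, f), slope = unname(coef(fit)["disp"]),
                 slope_ci = unname(ci), intercept = unname(coef(fit)[1]),
                 n = length(f)), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.4f, slope = %.3f Hz/mm [%.3f, %.3f], n = %d\n",
              x$pearson_r, x$slope, x$slope_ci[1], x$slope_ci[2], x$n))
  invisible(x)
}

#' Write a waveform as 16-bit PCM mono WAV
#'
#' @param wave an `audio_wave`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path) {
  s <- pmin(pmax(wave$samples, -1), 1)
  pcm <- as.integer(round(s * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")         # fmt chunk size
  writeBin(c(1L, 1L), con, size = 2, endian = "little")   # PCM, mono
  writeBin(as.integer(wave$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(wave$sample_rate * 2), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")  # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
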
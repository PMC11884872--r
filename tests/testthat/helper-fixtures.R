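# Shared fixtures, built in code.

default_cal <- function() calibration(mm_per_pixel = 0.1, rest_y_left = 300,
                                      rest_y_right = 300)

# Build an 8-digit pose stream whose left/right paw displacement (mm)
# follows the given traces; inverse of the engine's displacement map.
disp_to_stream <- function(disp_left, disp_right = rep(0, length(disp_left)),
                           fps = 70, cal = default_cal(), likelihood = 0.99) {
  n <- length(disp_left)
  offs <- c(-6, -2, 2, 6)
  y <- cbind(outer(cal$rest_y_left - disp_left / cal$mm_per_pixel, offs, `+`),
             outer(cal$rest_y_right - disp_right / cal$mm_per_pixel, offs, `+`))
  x <- matrix(200, n, 8)
  lik <- matrix(likelihood, n, 8)
  pose_stream(x, y, lik,
              bodyparts = c(paste0("left_digit", 1:4),
                            paste0("right_digit", 1:4)),
              fps = fps)
}

# Kinematic data frame straight from displacement samples (no smoothing).
disp_to_kin <- function(disp_left, fps = 70,
                        disp_right = rep(0, length(disp_left))) {
  n <- length(disp_left)
  data.frame(t = (seq_len(n) - 1) / fps, disp_left = disp_left,
             disp_right = disp_right, valid_left = rep(TRUE, n),
             valid_right = rep(TRUE, n))
}

# A small random pose stream for I/O round trips.
random_stream <- function(n = 100, p = 4, seed = 1) {
  set.seed(seed)
  pose_stream(matrix(runif(n * p, 0, 640), n, p),
              matrix(runif(n * p, 0, 480), n, p),
              matrix(runif(n * p), n, p),
              bodyparts = paste0("left_digit", seq_len(p)), fps = 70)
}

# Two-cluster planted trajectory sets for the clustering checks: two reach
# templates (low short vs high long) plus small jitter.
planted_two_cluster_trajectories <- function(n_each = 30, seed = 1,
                                             jitter_sd = 0.3) {
  set.seed(seed)
  mk <- function(apex, dur, n) lapply(seq_len(n), function(i) {
    len <- round(dur * 70)
    simulate_reach(apex, dur, 70, 0) + rnorm(len, 0, jitter_sd)
  })
  list(trajectories = c(mk(8, 0.5, n_each), mk(16, 1.0, n_each)),
       truth = rep(1:2, each = n_each))
}
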
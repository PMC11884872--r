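# Independent oracles, deliberately implemented differently from the
# package code paths they check.

# Brute-force excursion scan counting reach attempts and successes with
# return-to-start and refractory gating. Works on raw samples: finds
# maximal excursions above start_tolerance among valid samples, walks them
# in order, and re-arms after a success only once a below-band sample at or
# after the refractory deadline has occurred.
oracle_reach_counts <- function(t, disp, valid = rep(TRUE, length(disp)),
                                cfg = trial_config()) {
  keep <- as.logical(valid)
  t <- t[keep]; disp <- disp[keep]
  n <- length(disp)
  if (!n) return(c(attempts = 0L, successes = 0L))
  above <- disp > cfg$start_tolerance
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  exc_s <- starts[r$values]; exc_e <- ends[r$values]
  attempts <- 0L; successes <- 0L
  armed <- TRUE; rearm_t <- -Inf; prev_e <- 0L
  for (k in seq_along(exc_s)) {
    s <- exc_s[k]; e <- exc_e[k]
    if (!armed && s > prev_e + 1L) {
      gap <- (prev_e + 1L):(s - 1L)
      if (any(t[gap] >= rearm_t)) armed <- TRUE
    }
    if (armed) {
      attempts <- attempts + 1L
      cross <- which(disp[s:e] >= cfg$target_offset)[1]
      if (!is.na(cross)) {
        successes <- successes + 1L
        armed <- FALSE
        rearm_t <- t[s + cross - 1L] + cfg$refractory
      }
    }
    prev_e <- e
  }
  c(attempts = attempts, successes = successes)
}

# Random displacement sequences stressing the state machine: iid noise,
# random walks, and planted ramps with random gaps.
random_fsm_sequence <- function(seed) {
  set.seed(seed)
  len <- sample(5:200, 1)
  kind <- seed %% 3
  disp <- if (kind == 0) {
    runif(len, -2, 22)
  } else if (kind == 1) {
    pmin(pmax(cumsum(rnorm(len, 0, 3)), -2), 25)
  } else {
    d <- numeric(len); i <- 1
    while (i < len) {
      gap <- sample(0:20, 1)
      i <- i + gap
      ramp_len <- sample(4:30, 1)
      if (i + ramp_len > len) break
      apex <- runif(1, 3, 22)
      half <- ceiling(ramp_len / 2)
      up <- seq(0, apex, length.out = half)
      d[i:(i + ramp_len - 1)] <-
        c(up, rev(up))[seq_len(ramp_len)]
      i <- i + ramp_len
    }
    d
  }
  valid <- runif(len) > 0.05
  list(t = (seq_len(len) - 1) / 70, disp = disp, valid = valid)
}

# Cell-by-cell scan of a pose CSV's likelihood values; returns the
# (frame, bodypart) pairs a validator must reject.
oracle_bad_likelihood_cells <- function(lines) {
  h2 <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  p <- (length(h2) - 1) / 3
  bodyparts <- h2[-1][seq(1, 3 * p, by = 3)]
  bad <- NULL
  for (i in seq_along(lines[-(1:3)])) {
    cells <- strsplit(lines[i + 3], ",", fixed = TRUE)[[1]]
    for (j in seq_len(p)) {
      lik <- suppressWarnings(as.numeric(cells[1 + 3 * j]))
      if (is.finite(lik) && (lik < 0 || lik > 1))
        bad <- rbind(bad, data.frame(frame = as.integer(cells[1]),
                                     bodypart = bodyparts[j]))
    }
  }
  bad
}
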
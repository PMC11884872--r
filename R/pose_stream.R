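#' Construct a pose stream
#'
#' A pose stream holds one camera's keypoint trajectories: per frame, an
#' (x, y, likelihood) triple for every tracked bodypart (by default the four
#' digits of each forepaw, eight keypoints in all). Coordinates follow the
#' image convention: y increases downward, so upward paw motion means
#' decreasing y. Missing or non-finite coordinates are kept (to preserve
#' frame cadence for the real-time loop) but flagged with likelihood 0.
#'
#' @param x,y numeric matrices, frames x bodyparts, pixel coordinates.
#' @param likelihood numeric matrix in `[0, 1]`, same shape; `NA` becomes 0.
#' @param bodyparts character vector of keypoint names; defaults to the
#'   column names of `x`.
#' @param fps nominal frame rate (Hz), used to synthesize timestamps when
#'   `time` is not given.
#' @param time optional numeric vector of timestamps (s), non-decreasing.
#' @param frame optional integer vector of frame indices, strictly
#'   increasing; defaults to `0:(n-1)`.
#' @param scorer scorer label written to the CSV header.
#' @return An object of class `pose_stream`.
#' @seealso [read_pose_csv()], [write_pose_csv()], [replay_source()]
#' @export
pose_stream <- function(x, y, likelihood, bodyparts = colnames(x), fps = 70,
                        time = NULL, frame = NULL, scorer = "reachtone") {
  x <- as.matrix(x); y <- as.matrix(y); likelihood <- as.matrix(likelihood)
  if (!all(dim(x) == dim(y)) || !all(dim(x) == dim(likelihood)))
    stop("x, y and likelihood must have identical dimensions")
  n <- nrow(x); p <- ncol(x)
  if (is.null(bodyparts)) bodyparts <- paste0("bodypart", seq_len(p))
  if (length(bodyparts) != p)
    stop("need one bodypart name per column, got ", length(bodyparts),
         " names for ", p, " columns")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be > 0")
  if (is.null(frame)) frame <- seq_len(n) - 1L
  frame <- as.integer(frame)
  if (n > 1 && any(diff(frame) <= 0))
    stop("frame indices must be strictly increasing")
  if (is.null(time)) time <- frame / fps
  if (n > 1 && any(diff(time) < 0)) stop("timestamps must be non-decreasing")

  likelihood[!is.finite(likelihood)] <- 0
  bad <- is.finite(likelihood) & (likelihood < 0 | likelihood > 1)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("likelihood out of [0, 1] at frame %d, bodypart '%s'",
                 frame[idx[1]], bodyparts[idx[2]]))
  }
  # a keypoint with an unusable coordinate is missing: likelihood 0
  miss <- !is.finite(x) | !is.finite(y)
  likelihood[miss] <- 0
  dimnames(x) <- dimnames(y) <- dimnames(likelihood) <-
    list(NULL, bodyparts)

  structure(
    list(frame = frame, time = as.numeric(time), bodyparts = bodyparts,
         x = x, y = y, likelihood = likelihood, fps = fps, scorer = scorer),
    class = "pose_stream")
}

#' @export
print.pose_stream <- function(x, ...) {
  cat(sprintf("<pose_stream> %d frames, %d bodyparts, %.6g fps (%.2f s)\n",
              n_frames(x), length(x$bodyparts), x$fps,
              if (n_frames(x)) diff(range(x$time)) else 0))
  cat("  bodyparts:", paste(x$bodyparts, collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a pose stream
#' @param stream a `pose_stream`.
#' @return integer frame count.
#' @export
n_frames <- function(stream) length(stream$frame)

#' Extract one frame of a pose stream
#'
#' @param stream a `pose_stream`.
#' @param i frame position (1-based row within the stream).
#' @return A list with `frame`, `time`, `bodyparts`, and named numeric
#'   vectors `x`, `y`, `likelihood` — one timestamped frame of keypoints.
#' @export
get_frame <- function(stream, i) {
  stopifnot(i >= 1, i <= n_frames(stream))
  list(frame = stream$frame[i], time = stream$time[i],
       bodyparts = stream$bodyparts,
       x = stream$x[i, ], y = stream$y[i, ],
       likelihood = stream$likelihood[i, ])
}

#' Camera calibration for displacement extraction
#'
#' Maps pixel coordinates to millimetres and records each paw's resting
#' baseline (pixel y at rest). Displacement is computed as
#' `(rest_y - y) * mm_per_pixel`, so upward motion is positive.
#'
#' @param mm_per_pixel scale (mm per pixel), > 0.
#' @param rest_y_left,rest_y_right resting y (pixels) of each paw's digit
#'   centroid.
#' @return An object of class `calibration`.
#' @export
calibration <- function(mm_per_pixel = 0.1, rest_y_left = 300,
                        rest_y_right = 300) {
  if (!is.numeric(mm_per_pixel) || mm_per_pixel <= 0)
    stop("mm_per_pixel must be > 0")
  if (!is.finite(rest_y_left) || !is.finite(rest_y_right))
    stop("rest positions must be finite")
  structure(list(mm_per_pixel = mm_per_pixel, rest_y_left = rest_y_left,
                 rest_y_right = rest_y_right), class = "calibration")
}

# ---- CSV dialect -----------------------------------------------------------

# strsplit drops one trailing empty field; the sentinel comma absorbs that,
# so ragged rows ending in empty cells keep their true field count
split_csv_line <- function(line) strsplit(paste0(line, ","), ",",
                                          fixed = TRUE)[[1]]

#' Read a pose-estimation CSV
#'
#' Parses the standard three-header-row dialect (`scorer` / `bodyparts` /
#' `coords`), where the coords row cycles `x, y, likelihood` per bodypart
#' and column 0 carries the frame index. The four-header multi-animal
#' dialect (an `individuals` row) is detected and rejected. Missing cells
#' become keypoints with likelihood 0; a finite likelihood outside
#' `[0, 1]` is a validation error naming the frame and bodypart.
#'
#' @param path file path.
#' @param fps frame rate (Hz) used to synthesize timestamps (the dialect
#'   carries no time column).
#' @return A [pose_stream()].
#' @export
read_pose_csv <- function(path, fps = 70) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3)
    stop("malformed pose CSV: expected 3 header rows (scorer/bodyparts/coords), got ",
         length(lines), " lines")
  h1 <- split_csv_line(lines[1])
  h2 <- split_csv_line(lines[2])
  h3 <- split_csv_line(lines[3])
  if (tolower(h1[1]) != "scorer")
    stop("malformed header row 1: expected leading cell 'scorer', got '", h1[1], "'")
  if (tolower(h2[1]) == "individuals" || tolower(h3[1]) == "individuals")
    stop("multi-animal pose CSV (an 'individuals' header row) is not supported; ",
         "export the single-animal dialect")
  if (tolower(h2[1]) != "bodyparts")
    stop("malformed header row 2: expected leading cell 'bodyparts', got '", h2[1], "'")
  if (tolower(h3[1]) != "coords")
    stop("malformed header row 3: expected leading cell 'coords', got '", h3[1], "'")

  ncol_data <- length(h3)
  if (ncol_data < 4 || (ncol_data - 1) %% 3 != 0)
    stop("malformed header row 3: coords must cycle x,y,likelihood per bodypart")
  coords <- tolower(h3[-1])
  p <- (ncol_data - 1) / 3
  if (!identical(coords, rep(c("x", "y", "likelihood"), p)))
    stop("malformed header row 3: coords must cycle x,y,likelihood per bodypart")
  bodyparts <- h2[-1][seq(1, 3 * p, by = 3)]
  if (anyDuplicated(bodyparts))
    stop("malformed header row 2: duplicated bodypart names")

  data_lines <- lines[-(1:3)]
  n <- length(data_lines)
  x <- y <- lik <- matrix(NA_real_, n, p)
  frame <- integer(n)
  for (i in seq_len(n)) {
    cells <- split_csv_line(data_lines[i])
    if (length(cells) != ncol_data)
      stop(sprintf("ragged row at line %d: expected %d cells, got %d",
                   i + 3L, ncol_data, length(cells)))
    vals <- suppressWarnings(as.numeric(cells))
    frame[i] <- as.integer(vals[1])
    if (is.na(frame[i]))
      stop(sprintf("non-numeric frame index at line %d", i + 3L))
    x[i, ] <- vals[seq(2, ncol_data, by = 3)]
    y[i, ] <- vals[seq(3, ncol_data, by = 3)]
    lik[i, ] <- vals[seq(4, ncol_data, by = 3)]
  }
  bad <- is.finite(lik) & (lik < 0 | lik > 1)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    msg <- paste(sprintf("frame %d bodypart '%s' (likelihood %g)",
                         frame[idx[, 1]], bodyparts[idx[, 2]],
                         lik[bad]), collapse = "; ")
    stop("likelihood out of [0, 1]: ", msg)
  }
  lik[!is.finite(lik)] <- 0
  pose_stream(x, y, lik, bodyparts = bodyparts, fps = fps, frame = frame,
              scorer = h1[2])
}

#' Write a pose-estimation CSV
#'
#' Emits the three-header-row dialect read by [read_pose_csv()]. Numeric
#' fields are written with 17 significant digits so that a write/read
#' round trip reproduces every value; missing keypoints are written as
#' empty cells with likelihood 0.
#'
#' @param stream a non-empty [pose_stream()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(stream, path) {
  stopifnot(inherits(stream, "pose_stream"))
  if (n_frames(stream) == 0) stop("refusing to write an empty pose stream")
  p <- length(stream$bodyparts)
  fmt <- function(v) ifelse(is.finite(v), sprintf("%.17g", v), "")
  h1 <- paste(c("scorer", rep(stream$scorer, 3 * p)), collapse = ",")
  h2 <- paste(c("bodyparts", rep(stream$bodyparts, each = 3)), collapse = ",")
  h3 <- paste(c("coords", rep(c("x", "y", "likelihood"), p)), collapse = ",")
  body <- vapply(seq_len(n_frames(stream)), function(i) {
    cells <- as.vector(rbind(fmt(stream$x[i, ]), fmt(stream$y[i, ]),
                             fmt(stream$likelihood[i, ])))
    paste(c(stream$frame[i], cells), collapse = ",")
  }, character(1))
  writeLines(c(h1, h2, h3, body), path)
  invisible(path)
}

# ---- clocks and timed replay ----------------------------------------------

#' Simulated and wall clocks
#'
#' A clock is a list of closures: `now()` returns the current time in
#' seconds, `sleep_until(t)` blocks (wall clock) or jumps (simulated clock)
#' until `t`. The simulated clock makes every timed component of the
#' package exactly reproducible.
#'
#' @param start start time (s) of the simulated clock.
#' @return A list with `now` and `sleep_until` closures; class
#'   `sim_clock` or `wall_clock`.
#' @export
simulated_clock <- function(start = 0) {
  t <- start
  structure(list(
    now = function() t,
    sleep_until = function(target) {
      if (target > t) t <<- target
      invisible(t)
    }), class = c("sim_clock", "reachtone_clock"))
}

#' @rdname simulated_clock
#' @export
wall_clock <- function() {
  origin <- as.numeric(Sys.time())
  structure(list(
    now = function() as.numeric(Sys.time()) - origin,
    sleep_until = function(target) {
      dt <- target - (as.numeric(Sys.time()) - origin)
      if (dt > 0) Sys.sleep(dt)
      invisible(as.numeric(Sys.time()) - origin)
    }), class = c("wall_clock", "reachtone_clock"))
}

#' Timed replay of a pose stream
#'
#' Stands in for the camera: yields frames one by one at inter-frame
#' intervals of `diff(time) / speed` by the supplied clock. Under
#' [simulated_clock()] delivery times are exactly reproducible.
#'
#' @param stream a [pose_stream()].
#' @param clock a clock from [simulated_clock()] or [wall_clock()].
#' @param speed playback speed multiplier, > 0.
#' @return An object of class `replay_source` with closures `has_next()`,
#'   `next_frame()` (returns the frame as in [get_frame()] plus
#'   `delivery_time`), and `delivery_log()` (data frame of frame indices
#'   and delivery times so far).
#' @export
replay_source <- function(stream, clock = simulated_clock(), speed = 1) {
  stopifnot(inherits(stream, "pose_stream"))
  if (!is.numeric(speed) || speed <= 0) stop("speed must be > 0")
  n <- n_frames(stream)
  t0 <- clock$now()
  sched <- t0 + (stream$time - stream$time[1]) / speed
  i <- 0L
  log_t <- numeric(0)
  structure(list(
    has_next = function() i < n,
    next_frame = function() {
      if (i >= n) stop("pose source exhausted")
      i <<- i + 1L
      clock$sleep_until(sched[i])
      fr <- get_frame(stream, i)
      fr$delivery_time <- clock$now()
      log_t[i] <<- fr$delivery_time
      fr
    },
    delivery_log = function()
      data.frame(frame = stream$frame[seq_along(log_t)],
                 t_delivery = log_t),
    n = n), class = "replay_source")
}
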
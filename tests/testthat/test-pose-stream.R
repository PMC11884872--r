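test_that("the three-header-row dialect is parsed structurally", {
  lines <- c(
    "scorer,net,net,net,net,net,net",
    "bodyparts,left_digit1,left_digit1,left_digit1,left_digit2,left_digit2,left_digit2",
    "coords,x,y,likelihood,x,y,likelihood",
    paste(0:4, "10,20,0.9", "30,40,0.8", sep = ","))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, path)
  s <- read_pose_csv(path, fps = 70)
  expect_s3_class(s, "pose_stream")
  expect_equal(n_frames(s), 5)
  expect_equal(s$bodyparts, c("left_digit1", "left_digit2"))
  expect_equal(unname(s$x[1, ]), c(10, 30))
  expect_equal(s$time, (0:4) / 70)
})

test_that("write then read reproduces every numeric field", {
  s <- random_stream(n = 100, p = 4, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(s, path)
  s2 <- read_pose_csv(path, fps = s$fps)
  expect_equal(s2$x, s$x, tolerance = 1e-9)
  expect_equal(s2$y, s$y, tolerance = 1e-9)
  expect_equal(s2$likelihood, s$likelihood, tolerance = 1e-9)
  expect_identical(s2$frame, s$frame)
  expect_identical(s2$bodyparts, s$bodyparts)
})

test_that("a one-frame stream writes a 4-line file and empty streams refuse", {
  s <- random_stream(n = 1, p = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(s, path)
  expect_length(readLines(path), 4)

  empty <- s
  empty$frame <- integer(0); empty$time <- numeric(0)
  empty$x <- empty$y <- empty$likelihood <- empty$x[0, , drop = FALSE]
  path2 <- file.path(withr::local_tempdir(), "never.csv")
  expect_error(write_pose_csv(empty, path2), "empty")
  expect_false(file.exists(path2))
})

test_that("out-of-range likelihoods are rejected, matching a brute-force cell scan", {
  make_file <- function(liks) {
    lines <- c(
      "scorer,n,n,n,n,n,n",
      "bodyparts,a,a,a,b,b,b",
      "coords,x,y,likelihood,x,y,likelihood",
      vapply(seq_len(nrow(liks)), function(i)
        sprintf("%d,1,2,%g,3,4,%g", i - 1, liks[i, 1], liks[i, 2]),
        character(1)))
    path <- tempfile(fileext = ".csv")
    writeLines(lines, path)
    list(path = path, lines = lines)
  }

  f <- make_file(matrix(c(0.5, 0.9, 1.3, 0.2), 2, byrow = TRUE))
  expect_error(read_pose_csv(f$path), "frame 1.*'a'.*1\\.3")

  # property: the reader rejects exactly when the brute-force scan finds a
  # bad cell, over randomized likelihood tables
  for (seed in 1:20) {
    set.seed(seed)
    liks <- matrix(runif(10, -0.2, 1.2), 5, 2)
    f <- make_file(liks)
    bad <- oracle_bad_likelihood_cells(f$lines)
    if (is.null(bad)) {
      expect_silent(read_pose_csv(f$path))
    } else {
      expect_error(read_pose_csv(f$path), "likelihood out of")
    }
    unlink(f$path)
  }
})

test_that("malformed headers and ragged rows give located errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scorer,n,n,n",
               "individuals,m1,m1,m1",
               "bodyparts,a,a,a",
               "coords,x,y,likelihood",
               "0,1,2,0.5"), path)
  expect_error(read_pose_csv(path), "multi-animal")

  writeLines(c("scorer,n,n,n",
               "bodyparts,a,a,a",
               "coords,x,y,likelihood",
               "0,1,2,0.5",
               "1,1,2"), path)
  expect_error(read_pose_csv(path), "line 5")

  writeLines(c("scorer,n,n,n",
               "bodyparts,a,a,a",
               "coords,x,y,probability"), path)
  expect_error(read_pose_csv(path), "row 3")
})

test_that("missing cells become likelihood-0 keypoints, preserving cadence", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scorer,n,n,n",
               "bodyparts,a,a,a",
               "coords,x,y,likelihood",
               "0,1,2,0.9",
               "1,,,",
               "2,5,6,0.8"), path)
  s <- read_pose_csv(path)
  expect_equal(n_frames(s), 3)
  expect_equal(unname(s$likelihood[, 1]), c(0.9, 0, 0.8))
  expect_true(is.na(s$x[2, 1]))
})

test_that("timed replay delivers frames at exact simulated-clock times", {
  s <- random_stream(n = 10, p = 2)
  src <- replay_source(s, simulated_clock(), speed = 1)
  while (src$has_next()) src$next_frame()
  expect_equal(src$delivery_log()$t_delivery, (0:9) / 70)

  src2 <- replay_source(s, simulated_clock(), speed = 2)
  while (src2$has_next()) src2$next_frame()
  expect_equal(src2$delivery_log()$t_delivery, (0:9) / 140)

  # determinism: identical inputs give bitwise-identical delivery logs
  src3 <- replay_source(s, simulated_clock(), speed = 1)
  while (src3$has_next()) src3$next_frame()
  expect_identical(src3$delivery_log(), src$delivery_log())

  expect_error(replay_source(s, simulated_clock(), speed = 0), "speed")
})
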
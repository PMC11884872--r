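test_that("reach segmentation finds excursions with exact apexes", {
  cfg <- trial_config()
  ramp <- c(0, 5, 12, 20, 12, 5, 0)
  r <- detect_reaches(disp_to_kin(ramp), cfg, "left")
  expect_equal(n_reaches(r), 1)
  expect_equal(r$segments$apex, 20)

  expect_equal(n_reaches(detect_reaches(disp_to_kin(rep(0, 50)), cfg)), 0)
  expect_equal(n_reaches(detect_reaches(disp_to_kin(numeric(0)), cfg)), 0)
})

test_that("offline segmentation agrees with the simulator's planted reaches", {
  params <- learning_params(noise_sd = 0, dropout_rate = 0)
  ses <- simulate_session("m", 3, "feedback", params,
                          cohort_design(session_length = 120), seed = 13)
  rec <- run_session(ses$stream, ses$calibration)
  left <- detect_reaches(rec$kinematics, rec$config$trial, "left")
  right <- detect_reaches(rec$kinematics, rec$config$trial, "right")
  expect_equal(n_reaches(left), unname(ses$counts["left"]))
  expect_equal(n_reaches(right), unname(ses$counts["right"]))
})

test_that("alignment resamples to fixed length, preserving endpoints and peaks", {
  tri <- c(0, 5, 10, 15, 10, 5, 0)
  tm <- align_and_resample(list(tri), T_samples = 7)
  expect_equal(dim(tm$mat), c(1, 7))
  expect_equal(tm$mat[1, ], tri)   # already length T: unchanged

  tm2 <- align_and_resample(list(tri), T_samples = 25)
  expect_equal(tm2$mat[1, 1], 0)
  expect_equal(tm2$mat[1, 25], 0)
  one_sample_slope <- max(abs(diff(tri)))
  expect_lte(abs(max(tm2$mat) - 15), one_sample_slope)

  tm0 <- align_and_resample(list(), T_samples = 10)
  expect_equal(nrow(tm0$mat), 0)

  expect_warning(tm1 <- align_and_resample(list(tri, 5), T_samples = 10),
                 "excluded")
  expect_equal(nrow(tm1$mat), 1)
  expect_equal(attr(tm1, "n_excluded"), 1)
})

test_that("PCA embedding captures rank structure and reconstructs exactly", {
  set.seed(5)
  template <- simulate_reach(10, 1, 70, 0)
  scal <- runif(30, 0.5, 2)
  rank1 <- outer(scal, template)
  p1 <- pca_embed(rank1, k = 3)
  expect_gte(p1$variance_explained[1], 0.999)
  expect_true(all(diff(p1$variance_explained) <= 1e-12))

  m <- matrix(rnorm(20 * 12), 20, 12)
  pf <- pca_embed(m, k = 12)
  recon <- pf$scores %*% t(pf$loadings) +
    matrix(pf$center, 20, 12, byrow = TRUE)
  expect_lt(max(abs(recon - m)), 1e-8)

  dup <- rbind(m, m[1, , drop = FALSE])
  pd <- pca_embed(dup, k = 2)
  expect_equal(pd$scores[21, ], pd$scores[1, ])

  expect_error(pca_embed(m, k = 13), "k must be")
})

test_that("t-SNE is seed-deterministic and separates distinct blobs", {
  set.seed(9)
  blobs <- rbind(matrix(rnorm(30 * 2, 0), 30, 2),
                 matrix(rnorm(30 * 2, 12), 30, 2))
  e1 <- tsne_embed(blobs, perplexity = 8, seed = 42)
  e2 <- tsne_embed(blobs, perplexity = 8, seed = 42)
  expect_identical(e1, e2)

  grp <- rep(1:2, each = 30)
  within <- mean(dist(e1[grp == 1, ])) + mean(dist(e1[grp == 2, ]))
  between <- mean(as.matrix(dist(e1))[grp == 1, grp == 2])
  expect_gt(between, within / 2)

  expect_error(tsne_embed(matrix(rnorm(4), 2, 2), perplexity = 5),
               "perplexity")
})

test_that("GMM with BIC recovers planted cluster structure", {
  set.seed(31)
  two <- rbind(matrix(rnorm(40 * 2, 0, 1), 40, 2),
               matrix(rnorm(40 * 2, 8, 1), 40, 2))   # 8 SD separation
  cl <- gmm_cluster(two, K_range = 1:4, seed = 1)
  expect_equal(cl$K, 2)
  expect_gte(label_agreement(cl$labels, rep(1:2, each = 40)), 0.95)
  expect_equal(unname(cl$bic[paste0(cl$K)]), min(cl$bic))

  one <- matrix(rnorm(60 * 2), 60, 2)
  cl1 <- gmm_cluster(one, K_range = 1:4, seed = 1)
  expect_equal(cl1$K, 1)

  cl2 <- gmm_cluster(two, K_range = 1:4, seed = 1)
  expect_identical(cl2$labels, cl$labels)

  expect_error(gmm_cluster(two[1:3, ], K_range = 1:6), "at least")
})

test_that("label agreement is permutation-invariant", {
  lab <- c(1, 1, 2, 2, 3, 3)
  expect_equal(label_agreement(lab, c(3, 3, 1, 1, 2, 2)), 1)
  expect_equal(label_agreement(lab, lab), 1)
  expect_lt(label_agreement(c(1, 2, 1, 2, 1, 2), lab), 1)
})
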
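#' Segment reaches from a kinematic stream
#'
#' Offline counterpart of the trial machine's attempt counting: a reach is
#' a maximal excursion of the paw's displacement above `start_tolerance`
#' (on valid samples); its onset is the first crossing sample, its offset
#' the last sample still above the band, and its apex the maximum over the
#' excursion. Works for either paw, so the same rule yields the numerator
#' and denominator of the reach ratio.
#'
#' @param kin kinematic data frame from [stream_kinematics()] /
#'   [smooth_kinematics()], or the `kinematics` of a `session_record`.
#' @param cfg a [trial_config()].
#' @param paw `"left"` or `"right"`.
#' @param smoothed use the smoothed displacement column when present.
#' @return An object of class `reach_set`: data frame `segments` (onset_t,
#'   offset_t, apex, n_samples) and list `samples` of per-reach
#'   displacement series.
#' @export
detect_reaches <- function(kin, cfg = trial_config(),
                           paw = c("left", "right"), smoothed = TRUE) {
  paw <- match.arg(paw)
  col <- paste0("disp_", paw, if (smoothed &&
                                  !is.null(kin[[paste0("disp_", paw, "_smooth")]]))
    "_smooth" else "")
  disp <- kin[[col]]
  valid <- kin[[paste0("valid_", paw)]] %||% rep(TRUE, length(disp))
  empty <- structure(list(
    segments = data.frame(onset_t = numeric(0), offset_t = numeric(0),
                          apex = numeric(0), n_samples = integer(0)),
    samples = list(), paw = paw), class = "reach_set")
  if (!length(disp)) return(empty)
  above <- disp > cfg$start_tolerance & valid
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  samples <- Map(function(i, j) disp[i:j], starts, ends)
  structure(list(
    segments = data.frame(onset_t = kin$t[starts], offset_t = kin$t[ends],
                          apex = vapply(samples, max, numeric(1)),
                          n_samples = ends - starts + 1L),
    samples = samples, paw = paw), class = "reach_set")
}

#' @export
print.reach_set <- function(x, ...) {
  cat(sprintf("<reach_set> %d %s-paw reaches\n", nrow(x$segments), x$paw))
  invisible(x)
}

#' Number of reaches in a reach set
#' @param reaches a `reach_set`.
#' @return integer count.
#' @export
n_reaches <- function(reaches) nrow(reaches$segments)

#' Align reaches and resample to a common length
#'
#' Linearly time-warps each reach from onset to offset onto `T_samples`
#' points (endpoints preserved exactly), producing the trajectory matrix
#' that feeds PCA, t-SNE and clustering. Reaches of fewer than 2 samples
#' cannot be warped and are excluded; their count is reported as a warning
#' and in the `n_excluded` attribute.
#'
#' @param reaches a `reach_set` from [detect_reaches()], or a plain list
#'   of displacement series.
#' @param T_samples number of resampled points per trajectory, >= 2.
#' @param meta optional data frame (one row per reach) of metadata
#'   (mouse, day, group); excluded rows are dropped in step.
#' @return An object of class `trajectory_matrix`: `mat` (n_reaches x
#'   T_samples, mm) and `meta`.
#' @export
align_and_resample <- function(reaches, T_samples = 100, meta = NULL) {
  stopifnot(T_samples >= 2)
  samples <- if (inherits(reaches, "reach_set")) reaches$samples else reaches
  lens <- vapply(samples, length, integer(1))
  keep <- lens >= 2
  n_excluded <- sum(!keep)
  if (n_excluded)
    warning(n_excluded, " reach(es) of a single sample excluded from alignment")
  samples <- samples[keep]
  if (!is.null(meta)) meta <- meta[keep, , drop = FALSE]
  mat <- if (length(samples)) {
    t(vapply(samples, function(s)
      approx(seq(0, 1, length.out = length(s)), s,
             xout = seq(0, 1, length.out = T_samples))$y,
      numeric(T_samples)))
  } else {
    matrix(numeric(0), 0, T_samples)
  }
  structure(list(mat = mat, meta = meta), n_excluded = n_excluded,
            class = "trajectory_matrix")
}

#' @export
print.trajectory_matrix <- function(x, ...) {
  cat(sprintf("<trajectory_matrix> %d trajectories x %d samples\n",
              nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' Principal-component embedding of trajectories
#'
#' Mean-centers the trajectory matrix and projects it onto its first `k`
#' principal components.
#'
#' @param trajectories a `trajectory_matrix` or plain numeric matrix.
#' @param k number of components, `1 <= k <= min(n, T)`.
#' @return A list: `scores` (n x k), `loadings` (T x k),
#'   `variance_explained` (all components, non-increasing), `center`.
#' @export
pca_embed <- function(trajectories, k = 2) {
  m <- if (inherits(trajectories, "trajectory_matrix")) trajectories$mat
       else as.matrix(trajectories)
  if (k < 1 || k > min(dim(m)))
    stop("k must be in 1..min(n, T) = ", min(dim(m)))
  pr <- prcomp(m, center = TRUE, scale. = FALSE)
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x[, seq_len(k), drop = FALSE],
       loadings = pr$rotation[, seq_len(k), drop = FALSE],
       variance_explained = ve, center = pr$center)
}

#' Smallest component count reaching a variance target
#'
#' @param variance_explained per-component variance fractions.
#' @param threshold cumulative variance target (default 0.9).
#' @return integer k.
#' @export
choose_pca_k <- function(variance_explained, threshold = 0.9) {
  which(cumsum(variance_explained) >= threshold)[1]
}

#' Gaussian-mixture clustering with BIC model selection
#'
#' Fits full-covariance Gaussian mixtures to the feature matrix (PCA
#' scores) for each candidate cluster count and selects the K minimizing
#' the Bayesian information criterion (-2 log L + p log n); labels are
#' maximum-responsibility assignments. Fitting is delegated to mclust,
#' whose model-based hierarchical initialization makes the fit
#' deterministic.
#'
#' @param features numeric matrix (n x d) of PCA scores, or a vector.
#' @param K_range candidate cluster counts (default `1:6`).
#' @param seed seed (mclust initialization is deterministic; the seed
#'   guards any internal sampling).
#' @return An object of class `cluster_result`: `labels` (1-based),
#'   `K`, `bic` (per candidate K, minimize convention),
#'   `responsibilities` (n x K), `model` (the mclust fit).
#' @export
gmm_cluster <- function(features, K_range = 1:6, seed = 1) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < max(K_range))
    stop("need at least max(K_range) = ", max(K_range), " observations, got ", n)
  set.seed(seed)
  model_names <- if (ncol(features) == 1) "V" else "VVV"
  fit <- Mclust(features, G = K_range, modelNames = model_names,
                verbose = FALSE)
  if (is.null(fit)) stop("mixture fitting failed for all candidate K")
  bic <- -as.numeric(fit$BIC)          # mclust maximizes 2logL - p log n
  names(bic) <- rownames(fit$BIC)
  z <- fit$z
  if (is.null(z)) z <- matrix(1, n, 1)  # K = 1 has trivial responsibilities
  structure(list(labels = as.integer(fit$classification), K = fit$G,
                 bic = bic, responsibilities = z, model = fit),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> K = %d selected by BIC from {%s}\n",
              x$K, paste(names(x$bic), collapse = ", ")))
  invisible(x)
}

#' Best label agreement up to permutation
#'
#' Fraction of observations whose cluster label matches a reference
#' labeling under the best one-to-one relabeling (exhaustive over
#' permutations; intended for small K).
#'
#' @param labels,reference integer label vectors of equal length.
#' @return Agreement fraction in `[0, 1]`.
#' @export
label_agreement <- function(labels, reference) {
  stopifnot(length(labels) == length(reference))
  ks <- sort(unique(labels)); kr <- sort(unique(reference))
  if (length(ks) > 6) stop("label_agreement supports up to 6 clusters")
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  # map cluster labels onto reference labels (pad if fewer clusters)
  target <- if (length(kr) >= length(ks)) kr else c(kr, setdiff(ks, kr))
  best <- 0
  for (p in perms(target)) {
    mapped <- p[match(labels, ks)]
    best <- max(best, mean(mapped == reference, na.rm = TRUE))
  }
  best
}
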
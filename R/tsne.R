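#' t-SNE embedding for trajectory visualization
#'
#' Exact t-distributed stochastic neighbor embedding of the feature matrix
#' into two dimensions, used strictly for visualization of trajectory
#' similarity (clustering decisions use PCA scores, never this embedding).
#' Per-point Gaussian bandwidths are calibrated by bisection to the target
#' perplexity; the embedding is optimized by momentum gradient descent
#' with early exaggeration. Deterministic given `seed`.
#'
#' @param features numeric matrix (n x d); requires `n >= 3 * perplexity`.
#' @param perplexity effective neighborhood size.
#' @param seed integer seed for the random initialization.
#' @param max_iter gradient-descent iterations.
#' @param learning_rate step size.
#' @return An n x 2 matrix of embedding coordinates.
#' @export
tsne_embed <- function(features, perplexity = 10, seed = 1, max_iter = 500,
                       learning_rate = 200) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 3 * perplexity)
    stop("t-SNE requires n >= 3 * perplexity (n = ", n,
         ", perplexity = ", perplexity, ")")
  D2 <- as.matrix(dist(X))^2
  logU <- log(perplexity)

  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; beta_lo <- -Inf; beta_hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 1 / length(p) } else {
        H <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { beta_lo <- beta; beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2 }
      else { beta_hi <- beta; beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  set.seed(seed)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  exag <- 12
  for (iter in seq_len(max_iter)) {
    Peff <- if (iter <= 100) P * exag else P
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Peff - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    momentum <- if (iter <= 250) 0.5 else 0.8
    dY <- momentum * dY - learning_rate * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
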
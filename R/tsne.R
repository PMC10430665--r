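## Exact t-distributed stochastic neighbor embedding for the inspection
## map. The quadratic-time exact gradient is used (candidate sets after
## the screening funnel are a few hundred molecules); the input is the
## Tanimoto distance matrix reduced to 50 principal components first, and
## the 2-D map is for visual inspection only, never for clustering
## decisions.

#' 2-D t-SNE embedding of a distance matrix
#'
#' Defaults: perplexity 30, learning rate 200, 5000 iterations, PCA to 50
#' components en route. Deterministic for a fixed seed.
#'
#' @param matrix symmetric distance matrix (e.g. from
#'   [tanimoto_distance_matrix()]).
#' @param perplexity target perplexity; reduced with a warning when
#'   `n <= 3 * perplexity`.
#' @param learning_rate gradient-descent learning rate.
#' @param iterations number of gradient iterations.
#' @param seed RNG seed for the initial configuration.
#' @param pca_components components for the PCA preprocessing step.
#' @return n x 2 coordinate matrix (rownames preserved).
#' @export
tsne_embed <- function(matrix, perplexity = 30, learning_rate = 200,
                       iterations = 5000, seed = 1L, pca_components = 50L) {
  n <- nrow(matrix)
  if (n < 5) stop_fmt("t-SNE needs at least 5 points (got %d)", n)
  max_perp <- (n - 1) / 3
  if (perplexity > max_perp) {
    warn_fmt("perplexity %.0f too large for n = %d; reduced to %.1f",
             perplexity, n, max_perp)
    perplexity <- max_perp
  }
  X <- pca_embed(matrix, components = pca_components)
  D2 <- as.matrix(dist(X))^2

  # per-point precision by binary search on perplexity
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump < 1e-300) { H <- 0; p[] <- 1 / length(p) }
      else {
        H <- log(sump) + beta * sum(di * p) / sump
        p <- p / sump
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { betamin <- beta; beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2 }
      else { betamax <- beta; beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12

  set.seed(seed)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  gains <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  exaggeration <- 4; stop_exag <- min(100, iterations %/% 4)
  momentum <- 0.5
  for (it in seq_len(iterations)) {
    Pe <- if (it <= stop_exag) P * exaggeration else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - learning_rate * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
    if (it == 250) momentum <- 0.8
  }
  rownames(Y) <- rownames(matrix)
  colnames(Y) <- c("tsne1", "tsne2")
  Y
}
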
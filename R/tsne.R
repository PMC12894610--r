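# Exact (O(n^2)) t-SNE embedding for stimulus-level visualization.
# Figure-only: stochastic and hyperparameter-dependent, so it is never part
# of any quantitative claim the package makes. Implemented in-package with
# the standard ingredients: per-point precision search to match a target
# perplexity, symmetrized affinities, early exaggeration, and momentum
# gradient descent on the Student-t low-dimensional similarities.

tsne_p_matrix <- function(X, perplexity) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D2[i, -i]
    lo <- 0; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      w <- exp(-d * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(d * w) / sw
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    P[i, -i] <- w / sw
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' t-SNE embedding of a feature matrix (visualization only)
#'
#' Embeds items into 2 dimensions for plotting. Deterministic for a fixed
#' seed; excluded from all quantitative checks because the embedding is
#' stochastic and sensitive to hyperparameters.
#'
#' @param features Numeric matrix, items in rows (`n >= 5`).
#' @param seed Integer seed for the random initialization.
#' @param perplexity Target perplexity (default 10, suited to ~130 items).
#' @param n_iter Gradient-descent iterations (default 500).
#' @return Tibble with `dim1`, `dim2`.
#' @export
tsne_embed <- function(features, seed = 1L, perplexity = 10, n_iter = 500) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 5) abort("need at least 5 items", class = "affectdim_validation_error")
  if (perplexity >= (n - 1) / 3) perplexity <- max(2, floor((n - 1) / 3))
  if (any(!is.finite(X))) abort("features must be finite",
                                class = "affectdim_validation_error")
  P <- tsne_p_matrix(X, perplexity)
  run_seeded(derive_seed(seed, "tsne"), {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    G <- matrix(0, n, 2)          # momentum term
    gains <- matrix(1, n, 2)
    eta <- 200
    for (it in seq_len(n_iter)) {
      ex <- if (it <= 100) 4 else 1        # early exaggeration
      mom <- if (it <= 250) 0.5 else 0.8
      D2 <- as.matrix(dist(Y))^2
      W <- 1 / (1 + D2); diag(W) <- 0
      Q <- pmax(W / sum(W), 1e-12)
      L <- (ex * P - Q) * W
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      G <- mom * G - eta * gains * grad
      Y <- Y + G
      Y <- sweep(Y, 2, colMeans(Y))
    }
    tibble(dim1 = Y[, 1], dim2 = Y[, 2])
  })
}
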
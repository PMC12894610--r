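test_that("pca_fit recovers hand-computed variance splits", {
  withr::local_seed(1)
  # collinear two-column data: a single positive component
  x1 <- rnorm(10)
  f <- pca_fit(cbind(x1, 2 * x1))
  expect_equal(f$explained_variance_ratio[1], 1, tolerance = 1e-12)

  # cross-shaped points: covariance diag(2/3, 1/6) -> ratios 0.8 / 0.2
  pts <- rbind(c(1, 0), c(-1, 0), c(0, 0.5), c(0, -0.5))
  expect_equal(pca_fit(pts)$explained_variance_ratio, c(0.8, 0.2),
               tolerance = 1e-12)

  expect_error(pca_fit(matrix(1, 4, 3)), class = "affectdim_validation_error")
})

test_that("simplex rows lose one dimension after centering", {
  x <- simulate_stimuli("discrete", seed = 6, n_per_category = 8)
  P <- as.matrix(x[paste0("prob_", emotion_categories())])
  evr <- pca_fit(P)$explained_variance_ratio
  expect_lt(evr[5], 1e-12)
})

test_that("explained variance ratios are a nonincreasing unit partition", {
  withr::local_seed(31)
  for (rep in 1:10) {
    f <- pca_fit(matrix(rnorm(60), 12, 5))
    expect_equal(sum(f$explained_variance_ratio), 1, tolerance = 1e-10)
    expect_true(all(diff(f$explained_variance_ratio) <= 1e-12))
    # orthogonal loadings
    G <- crossprod(f$loadings)
    expect_equal(unname(G), diag(ncol(G)), tolerance = 1e-10)
    # sign convention: each component's largest-magnitude loading positive
    for (j in seq_len(ncol(f$loadings))) {
      v <- f$loadings[, j]
      expect_gt(v[which.max(abs(v))], 0)
    }
  }
})

test_that("pca_fit agrees with a covariance eigendecomposition oracle", {
  withr::local_seed(17)
  for (rep in 1:20) {
    X <- matrix(rnorm(50), 10, 5)
    f <- pca_fit(X)
    eig <- eigen(stats::cov(X), symmetric = TRUE)
    expect_equal(f$explained_variance_ratio,
                 eig$values / sum(eig$values), tolerance = 1e-8)
    for (j in 1:5) {
      expect_equal(abs(sum(f$loadings[, j] * eig$vectors[, j])), 1,
                   tolerance = 1e-8)
    }
  }
})

test_that("projection preserves geometry at full rank and truncates cleanly", {
  withr::local_seed(2)
  X <- matrix(rnorm(40), 8, 5)
  f <- pca_fit(X)
  expect_equal(unname(as.matrix(dist(pca_project(f, 5)))),
               unname(as.matrix(dist(X))), tolerance = 1e-10)

  # rank-2 data reconstructs exactly from 2 components
  B <- matrix(rnorm(16), 8, 2) %*% matrix(rnorm(10), 2, 5)
  f2 <- pca_fit(B)
  S <- pca_project(f2, 2)
  recon <- S %*% t(f2$loadings[, 1:2]) + rep(1, 8) %o% f2$center
  expect_equal(recon, B, tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(pca_project(f, 6), class = "affectdim_validation_error")
})

test_that("two-component reduction degrades discrete-regime cluster fit", {
  wins <- vapply(1:20, function(s) {
    x <- simulate_stimuli("discrete", seed = s)
    Z <- zscore_columns(as.matrix(x[paste0("prob_", emotion_categories())]))
    n5 <- nmi(contingency(x$category, cluster_stimuli(Z, 5)$assignments))
    S2 <- pca_project(pca_fit(Z), 2)
    n2 <- nmi(contingency(x$category, cluster_stimuli(S2, 5)$assignments))
    n5 > n2
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("t-SNE embedding is reproducible, 2-D, and class-separating", {
  blobs <- withr::with_seed(8, five_blobs(n_per = 6, sep = 10, sd = 0.4))
  e1 <- tsne_embed(blobs$X, seed = 2, n_iter = 250)
  e2 <- tsne_embed(blobs$X, seed = 2, n_iter = 250)
  expect_identical(e1, e2)
  expect_equal(ncol(e1), 2)
  expect_true(all(is.finite(e1$dim1)) && all(is.finite(e1$dim2)))

  # mean silhouette of the true labels on the embedding, computed directly
  Y <- as.matrix(e1)
  D <- as.matrix(dist(Y))
  sil <- vapply(seq_len(nrow(Y)), function(i) {
    own <- blobs$labels == blobs$labels[i]
    a <- mean(D[i, own & seq_len(nrow(Y)) != i])
    b <- min(vapply(setdiff(unique(blobs$labels), blobs$labels[i]),
                    function(l) mean(D[i, blobs$labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)

  expect_error(tsne_embed(matrix(rnorm(6), 3, 2)),
               class = "affectdim_validation_error")
})
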
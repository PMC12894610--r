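test_that("z-scoring standardizes columns and is idempotent", {
  expect_equal(unname(zscore_columns(cbind(c(1, 2, 3)))[, 1]), c(-1, 0, 1))
  X <- matrix(rnorm(40), 10, 4)
  Z <- zscore_columns(X)
  expect_equal(unname(colMeans(Z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(zscore_columns(Z)), unname(Z), tolerance = 1e-12)
  Xc <- cbind(a = rnorm(5), flat = rep(2, 5))
  expect_error(zscore_columns(Xc), "flat",
               class = "affectdim_validation_error")
})

test_that("complete linkage separates well-separated groups and handles edge k", {
  X <- cbind(c(0, 1, 10, 11))
  cl <- cluster_stimuli(X, 2)
  expect_true(same_partition(cl$assignments, c(1, 1, 2, 2)))
  expect_equal(cl$linkage, "complete")

  expect_equal(sort(unique(cluster_stimuli(X, 4)$assignments)), 1:4)
  expect_error(cluster_stimuli(X, 1), class = "affectdim_validation_error")
  expect_error(cluster_stimuli(X, 5), class = "affectdim_validation_error")
})

test_that("complete linkage agrees with a from-scratch linkage oracle (n <= 7)", {
  withr::local_seed(99)
  for (rep in 1:40) {
    n <- sample(4:7, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    k <- sample(2:(n - 1), 1)
    expect_true(same_partition(cluster_stimuli(X, k)$assignments,
                               complete_linkage_oracle(X, k)))
  }
})

test_that("contingency counts co-occurrences and validates lengths", {
  truth <- c("a", "a", "b", "b")
  expect_equal(unname(contingency(truth, c(1, 1, 2, 2))),
               rbind(c(2, 0), c(0, 2)))
  expect_equal(unname(contingency(truth, c(1, 1, 1, 1))), rbind(2, 2))
  expect_error(contingency(truth, c(1, 2)),
               class = "affectdim_validation_error")

  withr::local_seed(3)
  a <- sample(3, 30, replace = TRUE); b <- sample(4, 30, replace = TRUE)
  tab <- contingency(a, b)
  for (i in 1:3) for (j in 1:4) {
    expect_equal(tab[i, j], sum(a == i & b == j))
  }
})

test_that("nmi matches hand-derived values and conventions", {
  expect_equal(nmi(rbind(c(2, 0), c(0, 2))), 1)
  expect_equal(nmi(rbind(c(2, 3))), 0)          # single truth row
  expect_equal(nmi(cbind(c(2, 3))), 0)          # single cluster column
  expect_equal(nmi(rbind(c(3, 1), c(1, 3))), 0.1887219, tolerance = 1e-6)
  expect_error(nmi(rbind(c(-1, 2), c(1, 1))),
               class = "affectdim_validation_error")
})

test_that("nmi is symmetric, relabel-invariant, and 1 on self-partitions", {
  withr::local_seed(21)
  for (rep in 1:200) {
    tab <- random_contingency()
    expect_equal(nmi(tab), nmi(t(tab)), tolerance = 1e-12)
    expect_equal(nmi(tab[, sample(ncol(tab))]), nmi(tab), tolerance = 1e-12)
  }
  for (rep in 1:20) {
    part <- sample(3, 12, replace = TRUE)
    if (length(unique(part)) >= 2) {
      expect_equal(nmi(contingency(part, part)), 1, tolerance = 1e-12)
    }
  }
})

test_that("nmi curve peaks at the generating k on separable blobs", {
  for (s in 1:10) {
    blobs <- withr::with_seed(s, five_blobs())
    curve <- nmi_curve(blobs$X, blobs$labels, 2:8)
    expect_equal(curve$k[which.max(curve$nmi)], 5)
    expect_identical(curve, nmi_curve(blobs$X, blobs$labels, 2:8))
    # destroying the labels destroys the fit
    perm_nmi <- withr::with_seed(s + 100, {
      max(nmi_curve(blobs$X, sample(blobs$labels), 2:8)$nmi)
    })
    expect_lt(perm_nmi, max(curve$nmi))
  }
  expect_error(nmi_curve(matrix(rnorm(20), 10), rep(1:2, 5), k_range = 2:10),
               class = "affectdim_validation_error")
})

test_that("majority labels map clusters to modal categories with tie flags", {
  tab <- diag(3); dimnames(tab) <- list(c("a", "b", "c"), c("1", "2", "3"))
  m <- majority_cluster_labels(tab)
  expect_equal(m$category, c("a", "b", "c"))
  expect_false(any(m$tie))

  tie <- rbind(a = c(2, 0), b = c(2, 1))
  colnames(tie) <- c("c1", "c2")
  m2 <- majority_cluster_labels(tie)
  expect_equal(m2$category[m2$cluster == "c1"], "a")  # tie -> first canonical
  expect_true(m2$tie[m2$cluster == "c1"])

  empty <- cbind(c1 = c(2, 2), c2 = c(0, 0))
  rownames(empty) <- c("a", "b")
  expect_warning(m3 <- majority_cluster_labels(empty), "c2")
  expect_equal(nrow(m3), 1)
})

test_that("tight discrete clusters label as a bijection onto the categories", {
  for (s in 1:10) {
    x <- simulate_stimuli("discrete", seed = s, kappa = 100)
    Z <- zscore_columns(as.matrix(x[paste0("prob_", emotion_categories())]))
    tab <- contingency(x$category, cluster_stimuli(Z, 5)$assignments)
    m <- majority_cluster_labels(tab)
    expect_setequal(m$category, emotion_categories())
  }
})
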
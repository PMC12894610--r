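test_that("identical (config, seed) reproduces bit-identical datasets", {
  for (regime in c("discrete", "core_affect")) {
    a <- simulate_stimuli(regime, seed = 11)
    b <- simulate_stimuli(regime, seed = 11)
    expect_identical(a, b)
    expect_false(identical(a, simulate_stimuli(regime, seed = 12)))
  }
  x <- tiny_stimulus_table(10)
  expect_identical(simulate_subject_ratings(x, 5, seed = 3),
                   simulate_subject_ratings(x, 5, seed = 3))
})

test_that("every generated row satisfies the stimulus-table invariants", {
  for (s in 1:5) {
    for (regime in c("discrete", "core_affect")) {
      x <- simulate_stimuli(regime, seed = s, n_per_category = 8,
                            sigma_e = 2, kappa = 3)
      expect_silent(validate_stimulus_table(x))
      P <- as.matrix(x[paste0("prob_", emotion_categories())])
      expect_true(all(abs(rowSums(P) - 1) < 1e-12))
    }
  }
})

test_that("noise-free discrete regime returns the exact category centroids", {
  x <- simulate_stimuli("discrete", seed = 1, n_per_category = 4,
                        noise_free = TRUE)
  truth <- attr(x, "ground_truth")
  P <- as.matrix(x[paste0("prob_", emotion_categories())])
  expect_equal(unname(P), unname(truth$centroids[x$category, ]),
               tolerance = 0)
  # own-class mass 0.6, off-class 0.1, and centroids span 4 dimensions
  expect_equal(unname(diag(truth$centroids)), rep(0.6, 5))
  expect_equal(qr(scale(truth$centroids, scale = FALSE))$rank, 4)
})

test_that("noise-free core-affect probabilities are a rank-<=2 function of (v, a)", {
  x <- simulate_stimuli("core_affect", seed = 4, noise_free = TRUE)
  P <- as.matrix(x[paste0("prob_", emotion_categories())])
  expect_lte(qr(scale(P, scale = FALSE), tol = 1e-10)$rank, 2)
  # PCA sees at most 2 positive variance components
  evr <- pca_fit(P)$explained_variance_ratio
  expect_lt(sum(evr[3:5]), 1e-20)
  # stimuli with identical (v, a) receive identical probability rows
  i <- which(x$category == "fear")[1:2]
  expect_equal(x$valence[i[1]], x$valence[i[2]])
  expect_equal(unname(P[i[1], ]), unname(P[i[2], ]), tolerance = 0)
})

test_that("tight discrete clusters are recovered by clustering (NMI >= 0.8)", {
  nmis <- vapply(1:50, function(s) {
    x <- simulate_stimuli("discrete", seed = s, kappa = 100)
    Z <- zscore_columns(as.matrix(x[paste0("prob_", emotion_categories())]))
    nmi(contingency(x$category, cluster_stimuli(Z, 5)$assignments))
  }, numeric(1))
  expect_true(all(nmis >= 0.8))
})

test_that("subject ratings respect the scale and the noise-free limit", {
  x <- tiny_stimulus_table(6)
  r0 <- simulate_subject_ratings(x, n_subjects = 4, sigma_e = 0, seed = 1)
  expect_true(all(r0$valence == 5) && all(r0$arousal == 5))
  # for the correlation-1 check the stimulus means must vary
  x2 <- x; x2$valence <- seq(2, 7, 1); x2$arousal <- seq(7, 2, -1)
  r1 <- simulate_subject_ratings(x2, n_subjects = 6, sigma_e = 0, seed = 1)
  rel1 <- split_half_reliability(r1, n_runs = 5, seed = 1)
  expect_equal(rel1$per_run$correlation, rep(1, 10))

  rbig <- simulate_subject_ratings(x2, n_subjects = 30, sigma_e = 3, seed = 2)
  expect_true(all(rbig$valence >= 1 & rbig$valence <= 9))
  expect_true(all(rbig$arousal >= 1 & rbig$arousal <= 9))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(own_mass = 0.5, other_mass = 0.05),
               class = "affectdim_validation_error")
  expect_error(synthetic_config(kappa = -1))
  expect_error(synthetic_config(sigma_e = -0.1))
  expect_error(synthetic_config(endorsement_fidelity = 0))
})
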
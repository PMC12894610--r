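test_that("fold assignment is balanced, stratified, and deterministic", {
  expect_equal(sort(make_folds(10, 10, seed = 1)), 1:10)
  expect_identical(make_folds(40, 5, seed = 3), make_folds(40, 5, seed = 3))

  strata <- rep(emotion_categories(), each = 26)
  f <- make_folds(130, 10, strata = strata, seed = 2)
  expect_equal(unname(table(f)), rep(13L, 10), ignore_attr = TRUE)
  per_cat <- table(strata, f)
  expect_true(all(per_cat >= 2 & per_cat <= 3))

  expect_warning(make_folds(12, 10, strata = c(rep("a", 11), "b"), seed = 1),
                 "fewer items")
  expect_error(make_folds(5, 1), class = "affectdim_validation_error")
})

test_that("pooled R2 matches hand computation and degenerate cases", {
  Y <- cbind(c(1, 2, 3)); Yhat <- cbind(c(1, 2, 2))
  expect_equal(pooled_r2(Y, Yhat)$pooled_r2, 1 - 1 / 2)

  # two targets of unequal length folded into the pooled statistic by
  # stacking them as separate columns padded into one call each
  r1 <- pooled_r2(cbind(c(1, 2, 3)), cbind(c(1, 2, 2)))
  r2 <- pooled_r2(cbind(c(0, 2)), cbind(c(1, 1)))
  ssr <- sum(r1$per_target$ssr, r2$per_target$ssr)
  sst <- sum(r1$per_target$sst, r2$per_target$sst)
  expect_equal(r1$per_target$ssr, 1)
  expect_equal(r2$per_target$ssr, 2)
  expect_equal(r1$per_target$sst, 2)
  expect_equal(r2$per_target$sst, 2)
  expect_equal(1 - ssr / sst, 0.25)

  Y5 <- matrix(rnorm(50), 10, 5)
  expect_equal(pooled_r2(Y5, Y5)$pooled_r2, 1)
  M <- matrix(colMeans(Y5), 10, 5, byrow = TRUE)
  expect_equal(pooled_r2(Y5, M)$pooled_r2, 0)
  expect_error(pooled_r2(cbind(rep(1, 4)), cbind(rep(1, 4))),
               class = "affectdim_validation_error")
  expect_error(pooled_r2(Y5, Y5[1:5, ]), class = "affectdim_validation_error")
})

test_that("pooled R2 reduces to univariate R2 and respects permutations", {
  withr::local_seed(12)
  for (rep in 1:50) {
    y <- rnorm(20); yhat <- y + rnorm(20, 0, 0.5)
    expect_equal(pooled_r2(cbind(y), cbind(yhat))$pooled_r2,
                 r2_univariate(y, yhat), tolerance = 1e-12)
  }
  Y <- matrix(rnorm(60), 12, 5); Yh <- Y + matrix(rnorm(60, 0, 0.3), 12, 5)
  pc <- sample(5); pr <- sample(12)
  expect_equal(pooled_r2(Y[, pc], Yh[, pc])$pooled_r2,
               pooled_r2(Y, Yh)$pooled_r2, tolerance = 1e-12)
  expect_equal(pooled_r2(Y[pr, ], Yh[pr, ])$pooled_r2,
               pooled_r2(Y, Yh)$pooled_r2, tolerance = 1e-12)
})

test_that("linear CV recovers exact linear structure and rejects pure noise", {
  withr::local_seed(5)
  X <- matrix(rnorm(130 * 2), 130, 2)
  Y <- X %*% matrix(c(1, -2, 0.5, 3, 1, 1, -1, 0.2, 2, -0.5), 2, 5) + 4
  folds <- make_folds(130, 10, seed = 1)
  Yhat <- fit_predict_cv(X, Y, folds, family = "linear")
  expect_gte(pooled_r2(Y, Yhat)$pooled_r2, 0.999)

  noise_r2 <- vapply(1:50, function(s) {
    withr::with_seed(s, {
      Xn <- matrix(rnorm(130 * 2), 130, 2)
      Yn <- matrix(rnorm(130 * 5), 130, 5)
      fn <- make_folds(130, 10, seed = s)
      pooled_r2(Yn, fit_predict_cv(Xn, Yn, fn, family = "linear"))$pooled_r2
    })
  }, numeric(1))
  expect_true(all(noise_r2 <= 0.05))
})

test_that("training fit exceeds test fit for the linear family on average", {
  gaps <- vapply(1:20, function(s) {
    x <- simulate_stimuli("discrete", seed = s, n_per_category = 10)
    cmp <- compare_models(x, predictor_sets = "core_affect", n_folds = 5,
                          seed = s)
    cmp$summary$train_r2 - cmp$summary$test_fold_mean_r2
  }, numeric(1))
  expect_gt(mean(gaps), 0)
})

test_that("radial SVR beats linear regression on a sinusoidal signal", {
  withr::local_seed(6)
  X <- matrix(runif(120, -3, 3), 120, 1)
  Y <- cbind(sin(2 * X[, 1]) + rnorm(120, 0, 0.1))
  folds <- make_folds(120, 5, seed = 2)
  lin <- pooled_r2(Y, fit_predict_cv(X, Y, folds, family = "linear"))$pooled_r2
  rbf <- pooled_r2(Y, fit_predict_cv(X, Y, folds, family = "kernel",
                                     kernel = "radial"))$pooled_r2
  expect_gt(rbf, lin)
})

test_that("singular designs fall back to a ridge solution with a message", {
  withr::local_seed(8)
  X <- matrix(rnorm(40), 20, 2)
  X <- cbind(X, X[, 1])               # exact collinearity
  Y <- cbind(X[, 1] + rnorm(20, 0, 0.1))
  folds <- make_folds(20, 4, seed = 1)
  expect_message(Yhat <- fit_predict_cv(X, Y, folds, family = "linear"),
                 "ridge")
  expect_gt(pooled_r2(Y, Yhat)$pooled_r2, 0.8)
})

test_that("random-search tuning is deterministic and returns sane draws", {
  withr::local_seed(9)
  X <- matrix(runif(100, -2, 2), 50, 2)
  Y <- cbind(sin(X[, 1]) + 0.5 * X[, 2] + rnorm(50, 0, 0.1))
  folds <- make_folds(50, 5, seed = 4)
  h1 <- tune_svr(X, Y, folds, n_draws = 1, seed = 7, inner_folds = 3)
  h2 <- tune_svr(X, Y, folds, n_draws = 1, seed = 7, inner_folds = 3)
  expect_identical(h1, h2)
  expect_true(h1$cost >= 1e-2 && h1$cost <= 1e3)
  expect_true(h1$gamma >= 1e-3 && h1$gamma <= 10)
  expect_true(h1$epsilon >= 1e-3 && h1$epsilon <= 1)
  expect_error(tune_svr(X, Y, folds, n_draws = 0),
               class = "affectdim_validation_error")

  # more draws cannot hurt the inner-CV score of the selected draw
  h5 <- tune_svr(X, Y, folds, n_draws = 6, seed = 7, inner_folds = 3)
  expect_gte(attr(h5, "score"), attr(h1, "score"))
})

test_that("tuned radial SVR is not worse than defaults on kernel-friendly data", {
  diffs <- vapply(1:5, function(s) {
    withr::with_seed(s, {
      X <- matrix(runif(120, -3, 3), 60, 2)
      Y <- cbind(sin(2 * X[, 1]) + rnorm(60, 0, 0.1),
                 cos(X[, 2]) + rnorm(60, 0, 0.1))
      folds <- make_folds(60, 5, seed = s)
      h <- tune_svr(X, Y, folds, n_draws = 8, seed = s, inner_folds = 3)
      tuned <- pooled_r2(Y, fit_predict_cv(X, Y, folds, "kernel", "radial",
                                           hyper = h))$pooled_r2
      default <- pooled_r2(Y, fit_predict_cv(X, Y, folds, "kernel",
                                             "radial"))$pooled_r2
      tuned - default
    })
  }, numeric(1))
  expect_gte(mean(diffs), -0.02)
})
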
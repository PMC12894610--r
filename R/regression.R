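# Cross-validation engine for multi-output regression: fold construction,
# per-target fit/predict, pooled R-squared, and random-search tuning of
# support vector regression hyperparameters.

#' Stratified cross-validation fold assignment
#'
#' Assigns each item to one of `n_folds` folds, stratified by `strata` so
#' categories spread evenly, with a global balancing rule (per-stratum
#' remainders go to the currently smallest folds) that keeps overall fold
#' sizes within 1 of each other. Deterministic given `seed`; a single
#' assignment is meant to be reused across every model being compared.
#'
#' @param n Number of items.
#' @param n_folds Number of folds (default 10).
#' @param strata Optional category per item for stratification.
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1:n_folds`.
#' @export
make_folds <- function(n, n_folds = 10, strata = NULL, seed = 1L) {
  if (n_folds < 2 || n_folds > n) {
    abort("n_folds must lie in [2, n]", class = "affectdim_validation_error")
  }
  if (is.null(strata)) strata <- rep(1L, n)
  if (length(strata) != n) abort("strata must have length n",
                                 class = "affectdim_validation_error")
  run_seeded(derive_seed(seed, "folds"), {
    fold <- integer(n)
    totals <- numeric(n_folds)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      n_s <- length(idx)
      if (n_s < n_folds) {
        warn(paste0("stratum '", s, "' has fewer items (", n_s,
                    ") than folds; assigning it unstratified"))
      }
      base <- n_s %/% n_folds
      rem <- n_s %% n_folds
      counts <- rep(base, n_folds)
      if (rem > 0) {
        ord <- order(totals, runif(n_folds))  # smallest folds first, random ties
        counts[ord[seq_len(rem)]] <- base + 1
      }
      fold[sample(idx)] <- rep.int(seq_len(n_folds), counts)
      totals <- totals + counts
    }
    fold
  })
}

standardizer <- function(Xtr) {
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  function(X) scale(X, center = ctr, scale = scl)[, , drop = FALSE]
}

fit_predict_linear <- function(Xtr, Ytr, Xte) {
  A <- cbind(1, Xtr)
  fit <- stats::lm.fit(A, Ytr)
  beta <- as.matrix(fit$coefficients)
  if (anyNA(beta)) {
    inform("singular linear fit; using ridge fallback with penalty 1e-8")
    AtA <- crossprod(A) + diag(1e-8, ncol(A))
    beta <- solve(AtA, crossprod(A, Ytr))
  }
  cbind(1, Xte) %*% beta
}

fit_predict_svr <- function(Xtr, Ytr, Xte, kernel, hyper) {
  degree <- hyper$degree %||% 3
  gamma <- hyper$gamma %||% (1 / ncol(Xtr))
  preds <- map(seq_len(ncol(Ytr)), function(j) {
    fit <- e1071::svm(x = Xtr, y = Ytr[, j], type = "eps-regression",
                      kernel = kernel, cost = hyper$cost %||% 1,
                      gamma = gamma, epsilon = hyper$epsilon %||% 0.1,
                      degree = degree, scale = FALSE)
    as.numeric(stats::predict(fit, Xte))
  })
  do.call(cbind, preds)
}

#' Out-of-fold predictions for a multi-output regression
#'
#' For each fold, fits one model per outcome column on the training items
#' (predictors standardized with training-fold statistics) and predicts the
#' held-out items; predictions are assembled in the original item order.
#' Predicted probability columns are deliberately not renormalized: each
#' outcome is fit independently.
#'
#' @param X Numeric predictor matrix.
#' @param Y Numeric outcome matrix.
#' @param folds Fold index per item from [make_folds()].
#' @param family `"linear"` or `"kernel"` (epsilon-insensitive SVR).
#' @param kernel SVR kernel: `"radial"`, `"linear"`, `"polynomial"`,
#'   `"sigmoid"`.
#' @param hyper Named list of SVR hyperparameters (`cost`, `gamma`,
#'   `epsilon`, `degree`).
#' @param train_predictions Also return fitted values on each fold's own
#'   training items (for train-vs-test reporting).
#' @return Matrix of out-of-fold predictions shaped like `Y`; when
#'   `train_predictions` is `TRUE`, a list with `test` and `train` (the
#'   latter a list of per-fold matrices plus index vectors).
#' @export
fit_predict_cv <- function(X, Y, folds, family = c("linear", "kernel"),
                           kernel = "radial", hyper = list(),
                           train_predictions = FALSE) {
  family <- match.arg(family)
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), length(folds) == nrow(X))
  if (any(!is.finite(X)) || any(!is.finite(Y))) {
    abort("X and Y must be complete and numeric",
          class = "affectdim_validation_error")
  }
  Yhat <- matrix(NA_real_, nrow(Y), ncol(Y))
  train_out <- list()
  for (f in sort(unique(folds))) {
    te <- which(folds == f)
    tr <- which(folds != f)
    std <- standardizer(X[tr, , drop = FALSE])
    Xtr <- std(X[tr, , drop = FALSE])
    Xte <- std(X[te, , drop = FALSE])
    Yhat[te, ] <- if (family == "linear") {
      fit_predict_linear(Xtr, Y[tr, , drop = FALSE], Xte)
    } else {
      fit_predict_svr(Xtr, Y[tr, , drop = FALSE], Xte, kernel, hyper)
    }
    if (train_predictions) {
      fitted_tr <- if (family == "linear") {
        fit_predict_linear(Xtr, Y[tr, , drop = FALSE], Xtr)
      } else {
        fit_predict_svr(Xtr, Y[tr, , drop = FALSE], Xtr, kernel, hyper)
      }
      train_out[[as.character(f)]] <- list(idx = tr, fitted = fitted_tr)
    }
  }
  colnames(Yhat) <- colnames(Y)
  if (train_predictions) list(test = Yhat, train = train_out) else Yhat
}

#' Pooled R-squared over multiple outcome columns
#'
#' The multi-output fit statistic: residual and total sums of squares are
#' summed over all outcome columns before forming
#' `R2 = 1 - sum(SSR) / sum(SST)`, so targets with more variance weigh
#' more. SST for each target is taken about that target's observed mean
#' over the rows supplied (the grand mean for a headline value; test-fold
#' means when called per fold).
#'
#' @param Y Observed outcome matrix.
#' @param Yhat Predicted outcome matrix of the same shape.
#' @return A list of class `"pooled_r2"` with `pooled_r2` and a
#'   `per_target` tibble of SSR/SST.
#' @export
#' @examples
#' pooled_r2(cbind(c(1, 2, 3)), cbind(c(1, 2, 2)))
pooled_r2 <- function(Y, Yhat) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  if (!all(dim(Y) == dim(Yhat))) {
    abort("Y and Yhat must have the same shape",
          class = "affectdim_validation_error")
  }
  nms <- colnames(Y) %||% paste0("target_", seq_len(ncol(Y)))
  ssr <- colSums((Y - Yhat)^2)
  sst <- colSums(sweep(Y, 2, colMeans(Y))^2)
  zero <- which(sst == 0)
  if (length(zero) > 0) {
    abort(paste0("zero total sum of squares for target(s): ",
                 paste(nms[zero], collapse = ", ")),
          class = "affectdim_validation_error")
  }
  structure(
    list(pooled_r2 = 1 - sum(ssr) / sum(sst),
         per_target = tibble(target = nms, ssr = unname(ssr),
                             sst = unname(sst))),
    class = "pooled_r2"
  )
}

#' @export
print.pooled_r2 <- function(x, ...) {
  cat(sprintf("Pooled R-squared over %d targets: %.4f\n",
              nrow(x$per_target), x$pooled_r2))
  invisible(x)
}

draw_svr_hyper <- function(kernel) {
  lu <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  list(cost = lu(1e-2, 1e3), gamma = lu(1e-3, 10),
       epsilon = lu(1e-3, 1),
       degree = if (kernel == "polynomial") sample(2:4, 1) else 3)
}

#' Random-search tuning of SVR hyperparameters
#'
#' Samples `n_draws` hyperparameter sets from log-uniform ranges (cost in
#' `[1e-2, 1e3]`, kernel width gamma in `[1e-3, 10]`, epsilon in
#' `[1e-3, 1]`, polynomial degree in `{2, 3, 4}`) and scores each by pooled
#' R-squared under an inner 5-fold split of each outer training fold only —
#' held-out outer folds never inform the choice. Scores are averaged over
#' outer folds and the single best draw is returned.
#'
#' @param X,Y Predictor and outcome matrices.
#' @param folds Outer fold assignment from [make_folds()].
#' @param kernel SVR kernel name.
#' @param n_draws Number of random draws (default 50).
#' @param seed Integer seed.
#' @param inner_folds Inner split count (default 5).
#' @return The best hyperparameter list, with its inner-CV score attached
#'   as attribute `"score"`.
#' @export
tune_svr <- function(X, Y, folds, kernel = "radial", n_draws = 50,
                     seed = 1L, inner_folds = 5) {
  if (n_draws < 1) abort("n_draws must be >= 1",
                         class = "affectdim_validation_error")
  X <- as.matrix(X); Y <- as.matrix(Y)
  run_seeded(derive_seed(seed, "tune"), {
    draws <- map(seq_len(n_draws), function(i) draw_svr_hyper(kernel))
    outer <- sort(unique(folds))
    inner_assign <- map(outer, function(f) {
      tr <- which(folds != f)
      list(idx = tr, inner = make_folds(length(tr), min(inner_folds, length(tr)),
                                        seed = sample.int(2^31 - 2, 1)))
    })
    scores <- map_dbl(draws, function(h) {
      mean(map_dbl(inner_assign, function(a) {
        Yhat <- fit_predict_cv(X[a$idx, , drop = FALSE],
                               Y[a$idx, , drop = FALSE],
                               a$inner, family = "kernel", kernel = kernel,
                               hyper = h)
        pooled_r2(Y[a$idx, , drop = FALSE], Yhat)$pooled_r2
      }))
    })
    best <- which.max(scores)
    structure(draws[[best]], score = scores[best])
  })
}
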
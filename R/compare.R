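# Fold-paired comparison of predictor sets: can core affect (valence,
# arousal) explain the five-dimensional outcomes as well as the discrete
# label endorsements, or their combination?

predictor_columns <- function(set) {
  switch(set,
         core_affect = c("valence", "arousal"),
         discrete = endorse_cols(),
         combined = c("valence", "arousal", endorse_cols()),
         abort(paste0("unknown predictor set: ", set),
               class = "affectdim_validation_error"))
}

outcome_columns <- function(outcome) {
  switch(outcome,
         classifier_output = prob_cols(),
         self_report_labels = endorse_cols(),
         abort(paste0("unknown outcome: ", outcome),
               class = "affectdim_validation_error"))
}

# per-fold pooled R2 on held-out items, SST about test-fold observed means
fold_r2 <- function(Y, Yhat, folds) {
  map_dbl(sort(unique(folds)), function(f) {
    te <- folds == f
    pooled_r2(Y[te, , drop = FALSE], Yhat[te, , drop = FALSE])$pooled_r2
  })
}

# two-sided fold-paired sign-flip test on per-fold differences; exact
# enumeration of all 2^K sign patterns for the usual K = 10 folds
sign_flip_p <- function(d) {
  K <- length(d)
  obs <- abs(mean(d))
  if (K <= 14) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), K)))
    mean(abs(signs %*% d / K) >= obs - 1e-12)
  } else {
    flips <- matrix(sample(c(-1, 1), K * 2000, replace = TRUE), ncol = K)
    (1 + sum(abs(flips %*% d / K) >= obs - 1e-12)) / 2001
  }
}

#' Compare predictor sets by pooled cross-validated R-squared
#'
#' The package's central analysis. Each model predicts a five-dimensional
#' outcome (classifier probability vector, or self-reported label
#' endorsements) from one predictor set — `core_affect` (mean valence and
#' arousal), `discrete` (the five label endorsement fractions), or
#' `combined` (all seven) — with one regression per outcome column and fit
#' summarized by pooled cross-validated R-squared. All models share one
#' stratified fold assignment so per-fold R-squared values are paired, and
#' each pair of models is compared by the mean per-fold difference and an
#' exact fold-paired sign-flip test.
#'
#' @param stimuli A valid stimulus table.
#' @param outcome `"classifier_output"` (default) or `"self_report_labels"`.
#' @param predictor_sets Character vector among `"core_affect"`,
#'   `"discrete"`, `"combined"`.
#' @param family `"linear"` (default) or `"kernel"` (SVR).
#' @param kernel SVR kernel when `family = "kernel"`.
#' @param n_folds Cross-validation folds (default 10).
#' @param tune Tune SVR hyperparameters by random search (default `FALSE`,
#'   using SVR defaults).
#' @param n_draws Random-search draws when tuning (default 50).
#' @param seed Integer seed controlling folds and tuning.
#' @return A list of class `"affect_model_comparison"`: `per_fold` tibble
#'   (`model`, `fold`, `split`, `r2`), `summary` tibble (pooled train/test
#'   R-squared per model), `pairwise` tibble (mean fold-paired test
#'   difference and sign-flip p per model pair), `folds`, and the settings.
#' @export
#' @examples
#' x <- simulate_stimuli("discrete", seed = 3, n_per_category = 10)
#' cmp <- compare_models(x, n_folds = 5, seed = 3)
#' glance(cmp)
compare_models <- function(stimuli,
                           outcome = c("classifier_output", "self_report_labels"),
                           predictor_sets = c("core_affect", "discrete", "combined"),
                           family = c("linear", "kernel"),
                           kernel = "radial",
                           n_folds = 10, tune = FALSE, n_draws = 50,
                           seed = 1L) {
  stimuli <- validate_stimulus_table(stimuli)
  outcome <- match.arg(outcome)
  family <- match.arg(family)
  ycols <- outcome_columns(outcome)
  for (set in predictor_sets) {
    if (length(intersect(predictor_columns(set), ycols)) > 0) {
      abort(paste0("predictor set '", set,
                   "' overlaps the outcome columns; sets must be disjoint"),
            class = "affectdim_validation_error")
    }
  }
  Y <- as.matrix(stimuli[ycols])
  folds <- make_folds(nrow(stimuli), n_folds,
                      strata = as.character(stimuli$category), seed = seed)

  fits <- map(predictor_sets, function(set) {
    X <- as.matrix(stimuli[predictor_columns(set)])
    hyper <- list()
    if (family == "kernel" && tune) {
      hyper <- tune_svr(X, Y, folds, kernel = kernel, n_draws = n_draws,
                        seed = derive_seed(seed, paste0("tune_", set)))
    }
    pred <- fit_predict_cv(X, Y, folds, family = family, kernel = kernel,
                           hyper = hyper, train_predictions = TRUE)
    test_fold_r2 <- fold_r2(Y, pred$test, folds)
    train_fold_r2 <- map_dbl(pred$train, function(tr) {
      pooled_r2(Y[tr$idx, , drop = FALSE], tr$fitted)$pooled_r2
    })
    list(set = set, hyper = hyper,
         pooled_test = pooled_r2(Y, pred$test)$pooled_r2,
         test_fold_r2 = test_fold_r2, train_fold_r2 = unname(train_fold_r2))
  })
  names(fits) <- predictor_sets

  per_fold <- list_rbind(map(fits, function(f) {
    bind_rows(
      tibble(model = f$set, fold = seq_len(n_folds), split = "train",
             r2 = f$train_fold_r2),
      tibble(model = f$set, fold = seq_len(n_folds), split = "test",
             r2 = f$test_fold_r2)
    )
  }))
  summary <- list_rbind(map(fits, function(f) {
    tibble(model = f$set,
           train_r2 = mean(f$train_fold_r2),
           test_fold_mean_r2 = mean(f$test_fold_r2),
           test_pooled_r2 = f$pooled_test)
  }))
  pairs <- if (length(predictor_sets) > 1) utils::combn(predictor_sets, 2) else NULL
  pairwise <- if (is.null(pairs)) tibble() else {
    run_seeded(derive_seed(seed, "signflip"), {
      list_rbind(map(seq_len(ncol(pairs)), function(j) {
        a <- pairs[1, j]; b <- pairs[2, j]
        d <- fits[[a]]$test_fold_r2 - fits[[b]]$test_fold_r2
        tibble(model_a = a, model_b = b, mean_test_diff = mean(d),
               p_sign_flip = sign_flip_p(d))
      }))
    })
  }
  structure(
    list(per_fold = per_fold, summary = summary, pairwise = pairwise,
         folds = folds, outcome = outcome, family = family,
         kernel = if (family == "kernel") kernel else NA_character_,
         hyper = map(fits, "hyper"), seed = seed),
    class = "affect_model_comparison"
  )
}

#' @export
print.affect_model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (%s outcome, %s family%s, %d folds)\n",
              x$outcome, x$family,
              if (!is.na(x$kernel)) paste0(", ", x$kernel, " kernel") else "",
              length(unique(x$per_fold$fold))))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  if (nrow(x$pairwise) > 0) {
    cat("Fold-paired test R2 differences:\n")
    print(as.data.frame(x$pairwise), row.names = FALSE, digits = 4)
  }
  invisible(x)
}
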
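# Split-half reliability of aggregated valence and arousal ratings: if the
# rater panel is split in two and each half's per-video means are computed,
# how strongly do the two halves' stimulus-level estimates correlate?

#' Split-half reliability of aggregated affect ratings
#'
#' Runs `n_runs` random split-half replicates: the subjects are divided
#' into two disjoint equal halves (with an odd panel, one random subject is
#' dropped for that run), per-video mean valence and arousal are computed
#' within each half, and the halves are correlated across videos. The mean
#' correlation over runs estimates the reliability of the aggregated
#' stimulus-level affect norms.
#'
#' @param ratings Long-format subject ratings tibble.
#' @param n_runs Number of split-half replicates (default 10).
#' @param seed Integer seed.
#' @param method Correlation method: `"pearson"` (default) or
#'   `"spearman"`.
#' @return A list of class `"reliability_result"` with `per_run` (tibble of
#'   run, dimension, correlation), `mean_correlation` (named per
#'   dimension), `n_runs`, and `n_dropped` (subjects dropped per run for
#'   odd panels).
#' @export
#' @examples
#' x <- simulate_stimuli("discrete", seed = 2, n_per_category = 8)
#' r <- simulate_subject_ratings(x, n_subjects = 20, seed = 2)
#' split_half_reliability(r, seed = 2)
split_half_reliability <- function(ratings, n_runs = 10, seed = 1L,
                                   method = c("pearson", "spearman")) {
  ratings <- validate_subject_ratings(ratings)
  method <- match.arg(method)
  # sorted ids make the procedure invariant to input row order
  subjects <- sort(unique(ratings$subject_id))
  videos <- sort(unique(ratings$video_id))
  if (length(subjects) < 4) abort("need at least 4 subjects",
                                  class = "affectdim_validation_error")
  if (length(videos) < 3) abort("need at least 3 stimuli",
                                class = "affectdim_validation_error")
  n_half <- length(subjects) %/% 2
  n_dropped <- length(subjects) %% 2

  # wide matrices video x subject for fast half-means
  vmat <- matrix(NA_real_, length(videos), length(subjects),
                 dimnames = list(videos, subjects))
  amat <- vmat
  vmat[cbind(match(ratings$video_id, videos),
             match(ratings$subject_id, subjects))] <- ratings$valence
  amat[cbind(match(ratings$video_id, videos),
             match(ratings$subject_id, subjects))] <- ratings$arousal

  per_run <- run_seeded(derive_seed(seed, "split_half"), {
    list_rbind(map(seq_len(n_runs), function(run) {
      ord <- sample(length(subjects))
      h1 <- ord[seq_len(n_half)]
      h2 <- ord[n_half + seq_len(n_half)]
      rows <- map(c(valence = "valence", arousal = "arousal"), function(dim) {
        M <- if (dim == "valence") vmat else amat
        m1 <- rowMeans(M[, h1, drop = FALSE], na.rm = TRUE)
        m2 <- rowMeans(M[, h2, drop = FALSE], na.rm = TRUE)
        cor(m1, m2, use = "complete.obs", method = method)
      })
      tibble(run = run, dimension = names(rows),
             correlation = unlist(rows, use.names = FALSE))
    }))
  })
  mean_cor <- tapply(per_run$correlation, per_run$dimension, mean)
  structure(
    list(per_run = per_run,
         mean_correlation = mean_cor[c("valence", "arousal")],
         n_runs = as.integer(n_runs), method = method,
         n_dropped = n_dropped),
    class = "reliability_result"
  )
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Split-half reliability (%d runs, %s correlation)\n",
              x$n_runs, x$method))
  cat(sprintf("  valence: %.3f\n  arousal: %.3f\n",
              x$mean_correlation[["valence"]],
              x$mean_correlation[["arousal"]]))
  if (x$n_dropped > 0) cat("  (odd panel: 1 subject dropped per run)\n")
  invisible(x)
}
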
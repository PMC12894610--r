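# broom-style tidiers for the package's result objects.

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an accuracy summary
#' @param x An `"accuracy_summary"` object.
#' @param ... Unused.
#' @return Tibble with `category`, `rate`.
#' @export
tidy.accuracy_summary <- function(x, ...) x$per_category

#' @rdname tidy.accuracy_summary
#' @export
glance.accuracy_summary <- function(x, ...) {
  tibble(macro_rate = x$macro_rate, n_categories = nrow(x$per_category))
}

#' Tidy a clustering result
#' @param x An `"affect_clustering"` object.
#' @param ... Unused.
#' @return Tibble with `item`, `cluster`.
#' @export
tidy.affect_clustering <- function(x, ...) {
  tibble(item = seq_along(x$assignments), cluster = x$assignments)
}

#' @rdname tidy.affect_clustering
#' @export
glance.affect_clustering <- function(x, ...) {
  tibble(k = x$k, linkage = x$linkage, n = length(x$assignments))
}

#' Tidy an NMI permutation test
#' @param x An `"nmi_perm_test"` object.
#' @param ... Unused.
#' @return One-row tibble with the observed NMIs, difference, and p-value.
#' @export
tidy.nmi_perm_test <- function(x, ...) {
  tibble(nmi_a = x$nmi_a, nmi_b = x$nmi_b, observed_diff = x$observed,
         p_value = x$p_value, B = x$B, k = x$k)
}

#' @rdname tidy.nmi_perm_test
#' @export
glance.nmi_perm_test <- function(x, ...) tidy(x)

#' Tidy a PCA fit
#' @param x An `"affect_pca"` object.
#' @param matrix Which piece to return: `"loadings"`, `"scores"`, or
#'   `"eigenvalues"` (explained variance ratios).
#' @param ... Unused.
#' @return A tibble in long format.
#' @export
tidy.affect_pca <- function(x, matrix = c("loadings", "scores", "eigenvalues"),
                            ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    return(tibble(component = seq_along(x$explained_variance_ratio),
                  explained_variance_ratio = x$explained_variance_ratio,
                  cumulative = cumsum(x$explained_variance_ratio)))
  }
  M <- if (matrix == "loadings") x$loadings else x$scores
  as_tibble(M, rownames = if (matrix == "loadings") "variable" else NULL) |>
    mutate(row = if (matrix == "scores") dplyr::row_number() else NA_integer_,
           .before = 1) |>
    (\(d) if (matrix == "loadings") select(d, -"row") else d)()
}

#' @rdname tidy.affect_pca
#' @export
glance.affect_pca <- function(x, ...) {
  tibble(n_components = length(x$explained_variance_ratio),
         var_2_components = sum(x$explained_variance_ratio[1:2]))
}

#' Tidy a pooled R-squared result
#' @param x A `"pooled_r2"` object.
#' @param ... Unused.
#' @return Tibble of per-target SSR and SST.
#' @export
tidy.pooled_r2 <- function(x, ...) x$per_target

#' @rdname tidy.pooled_r2
#' @export
glance.pooled_r2 <- function(x, ...) {
  tibble(pooled_r2 = x$pooled_r2, n_targets = nrow(x$per_target))
}

#' Tidy a model comparison
#' @param x An `"affect_model_comparison"` object.
#' @param ... Unused.
#' @return The per-fold tibble (`model`, `fold`, `split`, `r2`).
#' @export
tidy.affect_model_comparison <- function(x, ...) x$per_fold

#' @rdname tidy.affect_model_comparison
#' @export
glance.affect_model_comparison <- function(x, ...) x$summary

#' Tidy a reliability result
#' @param x A `"reliability_result"` object.
#' @param ... Unused.
#' @return Tibble of per-run correlations.
#' @export
tidy.reliability_result <- function(x, ...) x$per_run

#' @rdname tidy.reliability_result
#' @export
glance.reliability_result <- function(x, ...) {
  tibble(valence = x$mean_correlation[["valence"]],
         arousal = x$mean_correlation[["arousal"]],
         n_runs = x$n_runs, method = x$method)
}
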
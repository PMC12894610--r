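# PCA reduction of classifier outputs to a candidate core-affect space.

#' Principal component analysis of a feature matrix
#'
#' Column-centered eigendecomposition of the sample covariance (no
#' rescaling — callers in the standard pipeline z-score upstream, which
#' makes covariance and correlation PCA coincide). Components are ordered
#' by explained variance, and each component's sign is fixed so that its
#' largest-magnitude loading is positive.
#'
#' Classifier probability rows sum to 1, so centering removes the simplex
#' direction and at most 4 of 5 components carry variance.
#'
#' @param features Numeric matrix or data frame, items in rows.
#' @return A list of class `"affect_pca"`: `loadings` (variable x
#'   component), `explained_variance_ratio`, `scores` (item x component),
#'   `center`, `sdev`.
#' @export
pca_fit <- function(features) {
  X <- as.matrix(features)
  if (nrow(X) < 2) abort("need at least 2 items",
                         class = "affectdim_validation_error")
  if (all(apply(X, 2, sd) == 0)) {
    abort("all columns are constant", class = "affectdim_validation_error")
  }
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    v <- p$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(p$rotation, 2, flip, "*")
  scores <- sweep(p$x, 2, flip, "*")
  evr <- p$sdev^2 / sum(p$sdev^2)
  structure(
    list(loadings = loadings, explained_variance_ratio = evr,
         scores = scores, center = p$center, sdev = p$sdev * flip^0),
    class = "affect_pca"
  )
}

#' @export
print.affect_pca <- function(x, ...) {
  cat("PCA fit:", nrow(x$scores), "items,", ncol(x$scores), "components\n")
  cat("explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = " "), "\n")
  invisible(x)
}

#' Project items onto the leading principal components
#'
#' Returns the item scores restricted to the first `n_components`
#' components. Feeding 2-component scores to [cluster_stimuli()] reproduces
#' the reduced-space re-clustering analysis: if five clusters truly arise
#' from two latent dimensions, clustering these scores should fit the
#' categories as well as the full space does.
#'
#' @param fit An `"affect_pca"` object.
#' @param n_components How many leading components to keep.
#' @return Numeric matrix, items x `n_components`.
#' @export
pca_project <- function(fit, n_components = 2) {
  stopifnot(inherits(fit, "affect_pca"))
  if (n_components > ncol(fit$scores)) {
    abort(paste0("n_components = ", n_components, " exceeds available ",
                 ncol(fit$scores)), class = "affectdim_validation_error")
  }
  fit$scores[, seq_len(n_components), drop = FALSE]
}
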
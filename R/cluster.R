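# Cluster-structure assessment of classifier outputs: z-scoring,
# complete-linkage hierarchical clustering, normalized mutual information
# (NMI) against the validated categories, k-range curves, and a permutation
# test comparing cluster fit between two feature representations.

#' Z-score the columns of a feature matrix
#'
#' Centers each column to mean 0 and scales to sample standard deviation 1
#' (n - 1 denominator). Constant columns are an error: they carry no
#' clustering information and would divide by zero.
#'
#' @param features Numeric matrix or data frame, items in rows.
#' @return Numeric matrix of the same shape.
#' @export
#' @examples
#' zscore_columns(cbind(a = c(1, 2, 3)))
zscore_columns <- function(features) {
  X <- as.matrix(features)
  if (!is.numeric(X)) abort("features must be numeric")
  sds <- apply(X, 2, sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad) > 0) {
    nm <- colnames(X)[bad] %||% as.character(bad)
    abort(paste0("zero-variance column(s): ", paste(nm, collapse = ", ")),
          class = "affectdim_validation_error")
  }
  scale(X, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Complete-linkage hierarchical clustering cut at k
#'
#' Agglomerative clustering with the complete-linkage rule (merge the two
#' groups whose maximum pairwise Euclidean distance is smallest), cut to
#' `k` clusters. Deterministic for distinct pairwise distances; with ties
#' the merge order follows the dendrogram construction of [stats::hclust()].
#'
#' @param features Numeric matrix or data frame, items in rows. Callers
#'   following the standard pipeline pass [zscore_columns()] output.
#' @param k Number of clusters, `2 <= k <= n`.
#' @return A list of class `"affect_clustering"` with `assignments`
#'   (integer cluster per item), `k`, `linkage = "complete"`, and the
#'   `hclust` tree.
#' @export
cluster_stimuli <- function(features, k) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (k < 2 || k > n) {
    abort(paste0("k must lie in [2, n]; got k = ", k, ", n = ", n),
          class = "affectdim_validation_error")
  }
  tree <- hclust(dist(X, method = "euclidean"), method = "complete")
  structure(
    list(assignments = unname(cutree(tree, k = k)), k = as.integer(k),
         linkage = "complete", tree = tree),
    class = "affect_clustering"
  )
}

#' @export
print.affect_clustering <- function(x, ...) {
  cat(sprintf("Complete-linkage clustering: %d items in %d clusters\n",
              length(x$assignments), x$k))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Truth-by-cluster contingency table
#'
#' @param truth Category per item (factor or character).
#' @param assignments Cluster index per item.
#' @return Integer matrix, truth categories in rows, clusters in columns.
#' @export
contingency <- function(truth, assignments) {
  if (length(truth) != length(assignments)) {
    abort("truth and assignments must have equal length",
          class = "affectdim_validation_error")
  }
  tr <- if (is.factor(truth)) truth else factor(truth)
  cl <- if (is.factor(assignments)) assignments else factor(assignments)
  unclass(table(tr, cl, dnn = NULL))
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information of a contingency table
#'
#' NMI between the two partitions summarized by a contingency table, using
#' natural-log entropies. The default `"average"` normalization is
#' `2 * MI / (H_rows + H_cols)`; `"min"`, `"max"` and `"geometric"` divide
#' MI by `min(H)`, `max(H)` and `sqrt(H_r * H_c)`. By convention the NMI of
#' any table with a zero-entropy marginal (a single cluster) is 0.
#'
#' @param tab Nonnegative count matrix (truth x cluster), or `truth` and
#'   `assignments` vectors via [contingency()].
#' @param normalization Normalization variant.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' nmi(rbind(c(2, 0), c(0, 2)))  # identical partitions: 1
nmi <- function(tab, normalization = c("average", "min", "max", "geometric")) {
  normalization <- match.arg(normalization)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!is.finite(tab))) {
    abort("contingency counts must be finite and nonnegative",
          class = "affectdim_validation_error")
  }
  n <- sum(tab)
  if (n < 1) abort("contingency table total must be >= 1",
                   class = "affectdim_validation_error")
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  hr <- entropy_nat(pi_)
  hc <- entropy_nat(pj_)
  if (hr == 0 || hc == 0) return(0)
  nz <- which(pij > 0, arr.ind = TRUE)
  mi <- sum(pij[nz] * log(pij[nz] / (pi_[nz[, 1]] * pj_[nz[, 2]])))
  mi <- max(mi, 0)  # guard tiny negative rounding
  denom <- switch(normalization,
                  average = (hr + hc) / 2,
                  min = min(hr, hc),
                  max = max(hr, hc),
                  geometric = sqrt(hr * hc))
  min(mi / denom, 1)
}

# fast path used inside permutation loops: both inputs integer codes
nmi_codes <- function(a, b, na, nb) {
  tab <- matrix(tabulate((a - 1L) * nb + b, nbins = na * nb),
                nrow = na, byrow = TRUE)
  nmi(tab)
}

#' NMI between a clustering and the validated categories over a k range
#'
#' Clusters once with complete linkage and cuts the same tree at every `k`,
#' reporting the NMI between each cut and the truth labels.
#'
#' @param features Numeric matrix, items in rows (typically z-scored).
#' @param truth Category per item.
#' @param k_range Integer vector of cluster counts, each in `[2, n - 1]`.
#' @return Tibble with `k` and `nmi`.
#' @export
nmi_curve <- function(features, truth, k_range = 2:10) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (any(k_range < 2) || any(k_range > n - 1)) {
    abort("k_range must lie within [2, n - 1]",
          class = "affectdim_validation_error")
  }
  tree <- hclust(dist(X), method = "complete")
  cuts <- cutree(tree, k = k_range)
  tibble(
    k = as.integer(k_range),
    nmi = map_dbl(seq_along(k_range),
                  function(i) nmi(contingency(truth, cuts[, i])))
  )
}

#' Label clusters by their modal category
#'
#' Maps each cluster to the category most represented in it. Ties resolve
#' to the earliest category in canonical order and are flagged; empty
#' cluster columns are skipped with a warning.
#'
#' @param tab Truth-by-cluster contingency matrix (rows in canonical
#'   category order).
#' @return Tibble with `cluster`, `category`, `n`, `tie`.
#' @export
majority_cluster_labels <- function(tab) {
  tab <- as.matrix(tab)
  cats <- rownames(tab) %||% as.character(seq_len(nrow(tab)))
  clusters <- colnames(tab) %||% as.character(seq_len(ncol(tab)))
  keep <- colSums(tab) > 0
  if (any(!keep)) {
    warn(paste0("skipping empty cluster(s): ",
                paste(clusters[!keep], collapse = ", ")))
  }
  rows <- map(which(keep), function(j) {
    col <- tab[, j]
    i <- which.max(col)  # first max = earliest canonical category
    tibble(cluster = clusters[j], category = cats[i], n = col[i],
           tie = sum(col == col[i]) > 1)
  })
  list_rbind(rows)
}

#' Permutation test for the NMI difference between two representations
#'
#' Tests whether feature representation A fits the validated categories
#' better than representation B, at a common cluster count `k`. Both
#' complete-linkage clusterings are computed once and held fixed; the
#' observed statistic is `NMI_A - NMI_B`. The null distribution jointly
#' permutes the truth labels across items `B` times, recomputing both NMIs
#' per permutation, and the one-sided p-value is
#' `(1 + #\{permuted >= observed\}) / (B + 1)`.
#'
#' Holding the clusterings fixed conditions the test on the observed
#' geometry and targets exactly the question "does representation A's
#' partition align with the categories more than representation B's".
#'
#' @param features_a,features_b Numeric matrices over the same items.
#' @param truth Category per item.
#' @param k Cluster count (default 5).
#' @param B Number of permutations (default 10000; must be >= 99).
#' @param seed Integer seed for the permutations.
#' @return A list of class `"nmi_perm_test"` with `observed`, `nmi_a`,
#'   `nmi_b`, `p_value`, `B`, `k`, and the permuted differences.
#' @export
nmi_permutation_test <- function(features_a, features_b, truth, k = 5,
                                 B = 10000, seed = 1L) {
  A <- as.matrix(features_a)
  Bm <- as.matrix(features_b)
  if (nrow(A) != nrow(Bm) || nrow(A) != length(truth)) {
    abort("features_a, features_b and truth must cover the same items",
          class = "affectdim_validation_error")
  }
  if (B < 99) abort("B must be >= 99", class = "affectdim_validation_error")
  ca <- cluster_stimuli(A, k)$assignments
  cb <- cluster_stimuli(Bm, k)$assignments
  tr <- as.integer(factor(truth))
  ntr <- max(tr)
  na_ <- max(ca); nb_ <- max(cb)
  nmi_a <- nmi_codes(tr, ca, ntr, na_)
  nmi_b <- nmi_codes(tr, cb, ntr, nb_)
  observed <- nmi_a - nmi_b
  perm <- run_seeded(derive_seed(seed, "nmi_perm"), {
    vapply(seq_len(B), function(i) {
      pt <- sample(tr)
      nmi_codes(pt, ca, ntr, na_) - nmi_codes(pt, cb, ntr, nb_)
    }, numeric(1))
  })
  structure(
    list(observed = observed, nmi_a = nmi_a, nmi_b = nmi_b,
         p_value = (1 + sum(perm >= observed)) / (B + 1),
         B = as.integer(B), k = as.integer(k), permuted = perm),
    class = "nmi_perm_test"
  )
}

#' @export
print.nmi_perm_test <- function(x, ...) {
  cat(sprintf(
    "NMI difference permutation test (k = %d)\n  NMI_A = %.4f, NMI_B = %.4f, difference = %.4f\n  one-sided p = %.4g (B = %d permutations)\n",
    x$k, x$nmi_a, x$nmi_b, x$observed, x$p_value, x$B))
  invisible(x)
}
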
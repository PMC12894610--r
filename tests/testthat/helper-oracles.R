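# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: explicit loops, from-scratch linkage, and
# textbook formulas.

# NMI by direct evaluation of the definitions: explicit double loop over
# cells, natural logs, arithmetic-mean normalization.
nmi_bruteforce <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      nij <- tab[i, j]
      if (nij > 0) {
        mi <- mi + (nij / n) * log((nij * n) / (sum(tab[i, ]) * sum(tab[, j])))
      }
    }
  }
  h <- function(m) {
    p <- m / n
    p <- p[p > 0]
    -sum(p * log(p))
  }
  hr <- h(rowSums(tab)); hc <- h(colSums(tab))
  if (hr == 0 || hc == 0) return(0)
  2 * mi / (hr + hc)
}

# From-scratch complete linkage: keep explicit cluster index sets, at each
# step recompute every between-cluster maximum pairwise distance, merge the
# minimum (lexicographic tie-break), stop at k clusters.
complete_linkage_oracle <- function(X, k) {
  X <- as.matrix(X)
  D <- as.matrix(dist(X))
  clusters <- as.list(seq_len(nrow(X)))
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  out <- integer(nrow(X))
  for (c in seq_along(clusters)) out[clusters[[c]]] <- c
  out
}

# partitions as unordered sets of item sets, for label-free comparison
partition_sets <- function(assign) {
  unname(lapply(split(seq_along(assign), assign), sort))
}
same_partition <- function(a, b) {
  setequal(lapply(partition_sets(a), paste, collapse = ","),
           lapply(partition_sets(b), paste, collapse = ","))
}

# textbook univariate R^2
r2_univariate <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

random_contingency <- function(max_dim = 6) {
  r <- sample(2:max_dim, 1)
  c_ <- sample(2:max_dim, 1)
  matrix(stats::rpois(r * c_, lambda = 3), r, c_)
}

# minimal valid stimulus table built by hand (n rows, cycling categories)
tiny_stimulus_table <- function(n = 5, probs = NULL) {
  cats <- emotion_categories()
  category <- rep_len(cats, n)
  if (is.null(probs)) {
    probs <- matrix(0, n, 5)
    probs[cbind(seq_len(n), match(category, cats))] <- 1
  }
  colnames(probs) <- paste0("prob_", cats)
  E <- matrix(0.2, n, 5, dimnames = list(NULL, paste0("endorse_", cats)))
  dplyr::bind_cols(
    tibble::tibble(video_id = sprintf("v%02d", seq_len(n)),
                   category = category,
                   valence = rep(5, n), arousal = rep(5, n)),
    tibble::as_tibble(E), tibble::as_tibble(probs)
  )
}

# well-separated five-blob feature matrix with known labels
five_blobs <- function(n_per = 10, sep = 8, sd = 0.5, d = 5) {
  centers <- diag(sep, 5)[, seq_len(d), drop = FALSE]
  labels <- rep(emotion_categories(), each = n_per)
  X <- centers[rep(1:5, each = n_per), , drop = FALSE] +
    matrix(rnorm(5 * n_per * d, 0, sd), ncol = d)
  list(X = X, labels = labels)
}
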
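# ggplot2 figures for each result type.

#' @export
ggplot2::autoplot

#' Plot an NMI-by-k curve
#'
#' @param curve Tibble from [nmi_curve()].
#' @return A ggplot.
#' @export
plot_nmi_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$nmi)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = curve$k) +
    ggplot2::labs(x = "number of clusters (k)",
                  y = "NMI with validated categories") +
    ggplot2::theme_minimal()
}

#' Heatmap of a confusion or endorsement matrix
#'
#' @param mat Numeric matrix with row/column names, or the tidy tibble
#'   from [endorsement_matrix()].
#' @return A ggplot tile heatmap.
#' @export
plot_confusion <- function(mat) {
  d <- if (is.matrix(mat)) {
    as_tibble(unclass(mat), rownames = "category") |>
      tidyr::pivot_longer(-"category", names_to = "label",
                          values_to = "value")
  } else {
    rename(as_tibble(mat), value = "mean_endorsement")
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$category,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.affect_pca <- function(object, truth = NULL, ...) {
  d <- tibble(pc1 = object$scores[, 1], pc2 = object$scores[, 2])
  if (!is.null(truth)) d$category <- as.character(truth)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance_ratio[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance_ratio[2])) +
    ggplot2::theme_minimal()
  if (is.null(truth)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(color = .data$category))
}

#' @export
autoplot.nmi_perm_test <- function(object, ...) {
  ggplot2::ggplot(tibble(diff = object$permuted),
                  ggplot2::aes(x = .data$diff)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = object$observed, color = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "permuted NMI difference",
                  subtitle = sprintf("observed = %.3f, p = %.4g",
                                     object$observed, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.affect_model_comparison <- function(object, split = "test", ...) {
  d <- filter(object$per_fold, .data$split == !!split)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$r2)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$fold), color = "grey75") +
    ggplot2::geom_point(ggplot2::aes(color = .data$model), size = 2) +
    ggplot2::labs(y = sprintf("%s pooled R² per fold", split),
                  x = "predictor set") +
    ggplot2::guides(color = "none") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.reliability_result <- function(object, ...) {
  ggplot2::ggplot(object$per_run,
                  ggplot2::aes(x = .data$dimension, y = .data$correlation)) +
    ggplot2::geom_boxplot(width = 0.4, outliers = FALSE) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::labs(y = "split-half correlation", x = NULL) +
    ggplot2::theme_minimal()
}
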
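# Manipulation-check summaries: endorsement matrices, accuracy rates, and
# argmax confusion matrices for classifier outputs.

#' Category-by-label mean endorsement matrix
#'
#' Entry (c, l) is the mean endorsement fraction of label l over stimuli of
#' validated category c. Because participants may endorse several labels
#' (plus "none of the above"), rows need not sum to 1.
#'
#' @param stimuli A valid stimulus table.
#' @param include_none Include the optional `none_of_the_above` column if
#'   present (default `FALSE`; it is excluded from analysis predictor sets).
#' @return Tidy tibble with `category`, `label`, `mean_endorsement`.
#' @export
endorsement_matrix <- function(stimuli, include_none = FALSE) {
  stimuli <- validate_stimulus_table(stimuli)
  check_no_empty_category(stimuli)
  cols <- endorse_cols()
  if (include_none && "endorse_none_of_the_above" %in% names(stimuli)) {
    cols <- c(cols, "endorse_none_of_the_above")
  }
  stimuli |>
    group_by(.data$category) |>
    summarise(across(dplyr::all_of(cols), mean), .groups = "drop") |>
    tidyr::pivot_longer(-"category", names_to = "label",
                        values_to = "mean_endorsement") |>
    mutate(label = sub("^endorse_", "", .data$label))
}

check_no_empty_category <- function(stimuli) {
  empty <- setdiff(emotion_categories(), unique(as.character(stimuli$category)))
  if (length(empty) > 0) {
    abort(paste0("no stimuli in category: ", paste(empty, collapse = ", ")),
          class = "affectdim_validation_error")
  }
  invisible(stimuli)
}

#' Per-category and macro accuracy rates
#'
#' The accuracy rate of a category is the probability of a stimulus being
#' labeled according to its validated category; the macro rate is the
#' unweighted mean of the per-category rates. Accepts either a square
#' confusion matrix (rates taken from the diagonal) or a named vector of
#' per-category rates.
#'
#' @param x A square numeric matrix with identical row/column category
#'   order, or a numeric vector of per-category rates.
#' @return A list of class `"accuracy_summary"` with `per_category`
#'   (tibble) and `macro_rate`.
#' @export
#' @examples
#' accuracy_summary(c(amusement = .338, disgust = .409, fear = .398,
#'                    neutral = .442, sexual_desire = .595))
accuracy_summary <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) {
      abort("confusion matrix must be square", class = "affectdim_validation_error")
    }
    if (!is.null(rownames(x)) && !is.null(colnames(x)) &&
        !identical(rownames(x), colnames(x))) {
      abort("confusion matrix row/column labels are misaligned",
            class = "affectdim_validation_error")
    }
    rates <- diag(x)
    names(rates) <- rownames(x) %||% paste0("category_", seq_along(rates))
  } else {
    rates <- x
    if (is.null(names(rates))) names(rates) <- paste0("category_", seq_along(rates))
  }
  structure(
    list(per_category = tibble(category = names(rates),
                               rate = unname(rates)),
         macro_rate = mean(rates)),
    class = "accuracy_summary"
  )
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat("Accuracy summary\n")
  for (i in seq_len(nrow(x$per_category))) {
    cat(sprintf("  %-15s %6.2f%%\n", x$per_category$category[i],
                100 * x$per_category$rate[i]))
  }
  cat(sprintf("  %-15s %6.2f%%\n", "macro", 100 * x$macro_rate))
  invisible(x)
}

#' Row-normalized argmax confusion matrix of classifier outputs
#'
#' Each stimulus is assigned the label with the largest classifier
#' probability; ties go to the first category in canonical order and are
#' counted in the `n_ties` attribute. Rows (true categories) are normalized
#' to sum to 1.
#'
#' @param stimuli A valid stimulus table.
#' @return A 5x5 matrix (rows = true category, columns = predicted label)
#'   with attribute `n_ties`.
#' @export
argmax_confusion <- function(stimuli) {
  stimuli <- validate_stimulus_table(stimuli)
  check_no_empty_category(stimuli)
  cats <- emotion_categories()
  P <- as.matrix(stimuli[prob_cols()])
  pred_idx <- max.col(P, ties.method = "first")
  n_ties <- sum(rowSums(P == P[cbind(seq_len(nrow(P)), pred_idx)]) > 1)
  if (n_ties > 0) {
    inform(paste0(n_ties, " argmax tie(s) broken by canonical category order"))
  }
  truth <- factor(as.character(stimuli$category), levels = cats)
  pred <- factor(cats[pred_idx], levels = cats)
  tab <- table(truth, pred)
  M <- sweep(unclass(tab), 1, rowSums(tab), "/")
  dimnames(M) <- list(cats, cats)
  attr(M, "n_ties") <- n_ties
  M
}
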
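#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted lesion discriminant
#'
#' @param x A `lesion_lda` object.
#' @param ... Unused.
#' @return A tibble with one row per selected feature: `term`, `estimate`
#'   (discriminant weight), and the class means.
#' @method tidy lesion_lda
#' @export
tidy.lesion_lda <- function(x, ...) {
  tibble::tibble(
    term = c(x$features, "(Intercept)"),
    estimate = c(unname(x$weights), x$intercept),
    mean_positive = c(unname(x$class_means["positive", ]), NA_real_),
    mean_negative = c(unname(x$class_means["negative", ]), NA_real_)
  )
}

#' @rdname tidy.lesion_lda
#' @method glance lesion_lda
#' @export
glance.lesion_lda <- function(x, ...) {
  tibble::tibble(n_features = length(x$features),
                 positive_class = x$positive_class)
}

#' Tidy an ROC result
#'
#' @param x A `lesion_roc` object.
#' @param ... Unused.
#' @return `tidy()`: the ROC curve as a tibble (`threshold`, `fpr`, `tpr`);
#'   `glance()`: a one-row tibble with `auc`, `accuracy`, `sensitivity`,
#'   `specificity`, `threshold`, `n`.
#' @method tidy lesion_roc
#' @export
tidy.lesion_roc <- function(x, ...) x$curve

#' @rdname tidy.lesion_roc
#' @method glance lesion_roc
#' @export
glance.lesion_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, accuracy = x$accuracy,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 threshold = x$threshold, n = length(x$scores))
}

#' @export
print.lesion_roc <- function(x, ...) {
  cat(sprintf("ROC analysis: n = %d (%d %s)\n", length(x$scores),
              sum(x$labels == x$positive), x$positive))
  cat(sprintf("  AUC = %.3f; at Youden operating point: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              x$auc, 100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' @export
print.lesion_lda <- function(x, ...) {
  cat(sprintf("Fisher linear discriminant (%s vs %s)\n",
              x$positive_class, x$negative_class))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}
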
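#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object A `lesion_roc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lesion_roc
#' @export
autoplot.lesion_roc <- function(object, ...) {
  df <- rbind(object$curve[, c("fpr", "tpr")], data.frame(fpr = 1, tpr = 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a segmentation over its image
#'
#' Renders the grayscale image with the mask boundary (and optionally a
#' reference mask boundary) overlaid.
#'
#' @param image Grayscale image matrix.
#' @param mask Logical mask to outline.
#' @param reference Optional second mask, drawn dashed.
#' @return A ggplot.
#' @export
plot_segmentation <- function(image, mask, reference = NULL) {
  img_df <- data.frame(
    row = rep(seq_len(nrow(image)), ncol(image)),
    col = rep(seq_len(ncol(image)), each = nrow(image)),
    value = as.vector(image)
  )
  outline_df <- function(m, which) {
    b <- trace_boundary(m)
    data.frame(row = b[, "row"], col = b[, "col"], which = which)
  }
  p <- ggplot2::ggplot(img_df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  p <- p + ggplot2::geom_path(
    data = outline_df(mask, "computed"),
    ggplot2::aes(x = .data$col, y = .data$row), color = "red", linewidth = 0.4)
  if (!is.null(reference))
    p <- p + ggplot2::geom_path(
      data = outline_df(reference, "reference"),
      ggplot2::aes(x = .data$col, y = .data$row), color = "cyan",
      linetype = "dashed", linewidth = 0.4)
  p
}

#' @importFrom rlang .data
NULL
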
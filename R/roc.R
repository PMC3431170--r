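#' ROC analysis of classifier scores
#'
#' Sweeps the decision threshold over the unique scores, computes the
#' sensitivity/1-specificity curve, the area under it by the trapezoidal
#' rule (identical to the Mann-Whitney pair-count statistic, with ties
#' counting one half), and the operating point maximizing Youden's
#' J = sensitivity + specificity - 1, at which accuracy, sensitivity and
#' specificity are reported.
#'
#' @param scores Numeric classifier scores (higher = more malignant).
#' @param labels Class labels; `positive` marks the positive class.
#' @param positive Positive-class label (default `"malignant"`).
#' @return An object of class `lesion_roc`: a list with `curve` (tibble of
#'   `threshold`, `fpr`, `tpr`), `auc`, `accuracy`, `sensitivity`,
#'   `specificity`, `threshold` (operating point), `scores`, `labels`.
#' @examples
#' roc_analysis(c(0.9, 0.8, 0.3, 0.1), c("malignant", "malignant", "benign", "benign"))$auc
#' @export
roc_analysis <- function(scores, labels, positive = "malignant") {
  stopifnot(length(scores) == length(labels))
  y <- labels == positive
  if (!any(y) || all(y)) stop("both classes must be present", call. = FALSE)
  np <- sum(y); nn <- sum(!y)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y) / np, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !y) / nn, 0)
  curve <- tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr),
                          tpr = c(0, tpr))
  # trapezoid over the sorted sweep; final point is (1, 1)
  xs <- c(curve$fpr, 1); ys <- c(curve$tpr, 1)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  j <- tpr + (1 - fpr) - 1
  best <- which.max(j)
  sens <- tpr[best]; spec <- 1 - fpr[best]
  acc <- (sens * np + spec * nn) / (np + nn)
  structure(list(curve = curve, auc = auc, accuracy = acc,
                 sensitivity = sens, specificity = spec,
                 threshold = thr[best], scores = scores,
                 labels = labels, positive = positive),
            class = "lesion_roc")
}

## DeLong placement values and AUC covariance machinery for paired ROC
## curves computed on the same lesions.
delong_placements <- function(scores, y) {
  xs <- scores[y]; ys <- scores[!y]
  m <- length(xs); n <- length(ys)
  v10 <- vapply(xs, function(x) (sum(x > ys) + 0.5 * sum(x == ys)) / n, 0)
  v01 <- vapply(ys, function(yv) (sum(xs > yv) + 0.5 * sum(xs == yv)) / m, 0)
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' DeLong paired comparison of two AUCs
#'
#' Tests whether two ROC curves computed from different score vectors on
#' the same lesions have equal AUC, using the nonparametric placement-value
#' covariance estimate and a two-sided z-test. With identical score
#' vectors the AUC difference and its variance are both zero; p = 1 is
#' returned by convention.
#'
#' @param roc_a,roc_b `lesion_roc` objects from [roc_analysis()], computed
#'   on the same lesions in the same order.
#' @return A one-row tibble: `auc_a`, `auc_b`, `auc_diff`, `variance`, `z`,
#'   `p_value`.
#' @export
compare_auc <- function(roc_a, roc_b) {
  stopifnot(inherits(roc_a, "lesion_roc"), inherits(roc_b, "lesion_roc"))
  if (length(roc_a$scores) != length(roc_b$scores) ||
      !identical(roc_a$labels, roc_b$labels))
    stop("ROC results are not paired on the same lesions", call. = FALSE)
  y <- roc_a$labels == roc_a$positive
  pa <- delong_placements(roc_a$scores, y)
  pb <- delong_placements(roc_b$scores, y)
  m <- sum(y); n <- sum(!y)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  L <- c(1, -1)
  v <- drop(t(L) %*% (s10 / m + s01 / n) %*% L)
  d <- pa$auc - pb$auc
  if (v <= .Machine$double.eps) {
    p <- if (abs(d) < .Machine$double.eps^0.5) 1 else 0
    z <- if (p == 1) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, auc_diff = d,
                 variance = v, z = z, p_value = p)
}
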
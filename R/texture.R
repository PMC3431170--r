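#' Gray-level co-occurrence matrix of a masked region
#'
#' Counts symmetric pixel pairs (both orders) at unit distance in one of the
#' four standard directions, restricted to pairs whose two pixels both lie
#' inside the mask, then normalizes to joint probabilities. Intensities are
#' quantized to `levels` equal-width bins over the min-max intensity range
#' within the mask (a constant region maps to a single level).
#'
#' Directions follow the usual image convention: 0 deg is horizontal,
#' angles increase counterclockwise, so 45 deg pairs a pixel with its
#' upper-right neighbor.
#'
#' @param image Grayscale image matrix.
#' @param mask Logical matrix, same shape; `NULL` uses the whole image
#'   (rectangle mode).
#' @param levels Number of gray levels after quantization (default 64; this
#'   materially changes feature values and should be reported with results).
#' @param d Pair distance in pixels (default 1).
#' @param theta Direction in degrees: 0, 45, 90 or 135.
#' @return A `levels` x `levels` matrix of class `glcm` summing to 1, with
#'   attributes `levels`, `d`, `theta`, `n_pairs`.
#' @export
compute_glcm <- function(image, mask = NULL, levels = 64L, d = 1L,
                         theta = c(0, 45, 90, 135)) {
  assert_gray_image(image)
  theta <- match.arg(as.character(theta[1]), c("0", "45", "90", "135"))
  theta <- as.numeric(theta)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  assert_mask(mask)
  stopifnot(all(dim(mask) == dim(image)), levels >= 2L, d >= 1L)
  q <- quantize_levels(image, mask, levels)
  off <- switch(as.character(theta),
                "0"   = c(0L, 1L),    # (drow, dcol): rightward
                "45"  = c(-1L, 1L),   # up-right
                "90"  = c(-1L, 0L),   # up
                "135" = c(-1L, -1L))  # up-left
  off <- off * d
  nr <- nrow(image); nc <- ncol(image)
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  a <- as.vector(q[r1, c1, drop = FALSE])
  b <- as.vector(q[r1 + off[1], c1 + off[2], drop = FALSE])
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L)
    stop("insufficient pairs inside the mask at this offset", call. = FALSE)
  counts <- matrix(0, levels, levels)
  tab <- table(factor(a[ok], levels = seq_len(levels)),
               factor(b[ok], levels = seq_len(levels)))
  counts <- counts + tab + t(tab)   # symmetric: count both orders
  p <- unname(counts / sum(counts))
  dimnames(p) <- NULL
  structure(p, class = c("glcm", "matrix"), levels = levels, d = d,
            theta = theta, n_pairs = sum(ok))
}

## Quantize in-mask intensities to 1..levels over the in-mask min-max range;
## out-of-mask pixels become NA.
quantize_levels <- function(image, mask, levels) {
  vals <- image[mask]
  lo <- min(vals); hi <- max(vals)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  if (hi == lo) {
    q[mask] <- 1L
  } else {
    q[mask] <- pmin(as.integer(floor((image[mask] - lo) / (hi - lo) * levels)) + 1L,
                    levels)
  }
  q
}

#' The 13 Haralick texture measures, averaged over directions
#'
#' Computes, for each supplied co-occurrence matrix, the 13 classic texture
#' statistics and returns their average over the four directions: angular
#' second moment, contrast, correlation, inverse difference moment, sum
#' average, sum variance, sum entropy, entropy, difference average,
#' difference variance, difference entropy, and the two information
#' measures of correlation. Entropies use the natural logarithm with
#' \eqn{0 \log 0 := 0}; the inner expression of the second information
#' measure is clamped at 0 before the square root. Sum variance is the
#' variance of the gray-sum distribution about the sum average, and
#' difference variance the variance of the gray-difference distribution
#' (the common readings of the original definitions).
#'
#' @param glcms A list of `glcm` matrices (one per direction) from
#'   [compute_glcm()], or a single `glcm`.
#' @return A one-row tibble with the 13 named features.
#' @export
haralick_features <- function(glcms) {
  if (inherits(glcms, "glcm")) glcms <- list(glcms)
  levels <- unique(vapply(glcms, attr, 1, "levels"))
  if (length(levels) != 1L)
    stop("all GLCMs must share the same number of levels", call. = FALSE)
  per_dir <- purrr::map(glcms, haralick_one)
  out <- purrr::reduce(per_dir, `+`) / length(per_dir)
  tibble::as_tibble(as.list(out))
}

## 13 measures of one normalized symmetric GLCM (vectorized; the test suite
## carries a literal double-loop oracle for these formulas).
haralick_one <- function(p) {
  G <- nrow(p)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(G) * px); muy <- sum(seq_len(G) * py)
  sx <- sqrt(sum((seq_len(G) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(G) - muy)^2 * py))
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  # sum and difference distributions
  psum <- vapply(2:(2 * G), function(k) sum(p[i + j == k]), 0)
  ks <- 2:(2 * G)
  pdiff <- vapply(0:(G - 1), function(k) sum(p[abs(i - j) == k]), 0)
  kd <- 0:(G - 1)
  asm <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sx > 0 && sy > 0) (sum(i * j * p) - mux * muy) / (sx * sy) else 0
  idm <- sum(p / (1 + (i - j)^2))
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- -sum(xlogx(psum))
  entropy <- -sum(xlogx(p))
  difference_average <- sum(kd * pdiff)
  difference_variance <- sum((kd - difference_average)^2 * pdiff)
  difference_entropy <- -sum(xlogx(pdiff))
  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(p * ifelse(pxy > 0, log(pxy), 0))
  hxy2 <- -sum(xlogx(pxy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(angular_second_moment = asm, contrast = contrast,
    correlation = correlation, inverse_difference_moment = idm,
    sum_average = sum_average, sum_variance = sum_variance,
    sum_entropy = sum_entropy, entropy = entropy,
    difference_average = difference_average,
    difference_variance = difference_variance,
    difference_entropy = difference_entropy,
    info_measure_corr_1 = imc1, info_measure_corr_2 = imc2)
}

#' Direction-averaged texture features of a segmented lesion
#'
#' Convenience wrapper: builds the four unit-distance GLCMs (0, 45, 90,
#' 135 degrees) over the masked lesion and returns the direction-averaged
#' 13 Haralick measures.
#'
#' @inheritParams compute_glcm
#' @return A one-row tibble with 13 columns.
#' @examples
#' ph <- make_phantom(phantom_spec(texture_heterogeneity = 10, seed = 3))
#' texture_features(ph$image, ph$mask)
#' @export
texture_features <- function(image, mask, levels = 64L, d = 1L) {
  glcms <- purrr::map(c(0, 45, 90, 135),
                      function(th) compute_glcm(image, mask, levels, d, th))
  haralick_features(glcms)
}
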
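#' Radial-length profile of a lesion mask
#'
#' Traces the ordered 8-connected boundary of a single-component mask and
#' returns the Euclidean distance from the area centroid of the mask to
#' each boundary pixel, in trace order (order matters for the spiculation
#' measure, which differences consecutive radii).
#'
#' @param mask Logical matrix with one connected component.
#' @return A list of class `radial_profile` with `r` (radial lengths),
#'   `center` (centroid, c(row, col)), `mu_r` (mean radius) and `boundary`
#'   (n x 2 matrix of boundary pixel coordinates).
#' @export
radial_profile <- function(mask) {
  b <- trace_boundary(mask)
  if (nrow(b) < 4L) stop("contour too small", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  center <- colMeans(idx)  # (row, col) area centroid
  r <- sqrt((b[, "row"] - center[1])^2 + (b[, "col"] - center[2])^2)
  if (any(r <= 0)) stop("degenerate contour: zero radial length", call. = FALSE)
  structure(list(r = r, center = center, mu_r = mean(r), boundary = b),
            class = "radial_profile")
}

## Chain-code perimeter of an ordered boundary trace: 1 per axial step,
## sqrt(2) per diagonal step, closing the loop.
chain_perimeter <- function(b) {
  n <- nrow(b)
  i2 <- c(2:n, 1)
  dr <- abs(b[i2, 1] - b[, 1]); dc <- abs(b[i2, 2] - b[, 2])
  sum(ifelse(dr + dc == 2 & dr == 1, sqrt(2), pmax(dr, dc)))
}

## Convex hull area in pixel-area units: hull of the 4 corners of every
## boundary pixel, so a convex digital shape has hull area equal to its
## pixel count (a 20 x 40 rectangle gives exactly 800).
convex_area <- function(b) {
  pts <- rbind(
    cbind(b[, 1] - 0.5, b[, 2] - 0.5), cbind(b[, 1] - 0.5, b[, 2] + 0.5),
    cbind(b[, 1] + 0.5, b[, 2] - 0.5), cbind(b[, 1] + 0.5, b[, 2] + 0.5))
  h <- grDevices::chull(pts[, 2], pts[, 1])
  abs(shoelace_area(pts[h, 2], pts[h, 1]))
}

#' The 8 morphological descriptors of a lesion
#'
#' Computes, from a single-component binary mask:
#' \describe{
#'   \item{p1_compactness}{\eqn{P^2 / (4 \pi S)} with chain-code perimeter
#'     P and pixel-count area S; 1 for a perfect disk.}
#'   \item{p2_spiculation}{mean absolute difference of consecutive radial
#'     lengths, \eqn{(1/N) \sum |r_i - r_{i+1}|} with wraparound.}
#'   \item{p3_extent}{S over the area of the axis-aligned bounding box.}
#'   \item{p4_elongation}{min(H, L) / max(H, L) of the bounding box.}
#'   \item{p5_solidity}{S over the convex hull area.}
#'   \item{p6_circularity}{mean absolute deviation of the radial lengths
#'     from their mean, \eqn{(1/N) \sum |r_i - \mu_r|}.}
#'   \item{p7_radial_entropy}{entropy (natural log) of the histogram of
#'     \eqn{r_i / \max r_i} over `radial_bins` equal-width bins on
#'     \[0, 1\]; near 0 for a disk, larger for irregular outlines.}
#'   \item{p8_eccentricity}{eccentricity of the ellipse with the same
#'     second moments as the region, \eqn{\sqrt{1 - (b/a)^2}}.}
#' }
#' p2 and p6 are in pixels and scale with lesion size; the ratio features
#' are scale-free.
#'
#' @param mask Logical matrix with one connected component.
#' @param radial_bins Histogram bins for p7 (default 10).
#' @return A one-row tibble with columns `p1_compactness` ...
#'   `p8_eccentricity`.
#' @examples
#' ph <- make_phantom(phantom_spec(n_spicules = 8, spicule_amplitude = 0.3,
#'                                 lesion_class = "malignant", seed = 4))
#' shape_features(ph$mask)
#' @export
shape_features <- function(mask, radial_bins = 10L) {
  rp <- radial_profile(mask)
  b <- rp$boundary
  r <- rp$r
  n <- length(r)
  S <- sum(mask)
  P <- chain_perimeter(b)
  rows <- range(b[, 1]); cols <- range(b[, 2])
  H <- diff(rows) + 1; L <- diff(cols) + 1
  i2 <- c(2:n, 1)
  rn <- r / max(r)
  breaks <- seq(0, 1, length.out = radial_bins + 1)
  h <- tabulate(pmin(findInterval(rn, breaks, rightmost.closed = TRUE),
                     radial_bins), radial_bins)
  ph <- h / sum(h)
  p7 <- -sum(ifelse(ph > 0, ph * log(ph), 0))
  tibble::tibble(
    p1_compactness = P^2 / (4 * pi * S),
    p2_spiculation = mean(abs(r - r[i2])),
    p3_extent = S / (H * L),
    p4_elongation = min(H, L) / max(H, L),
    p5_solidity = S / convex_area(b),
    p6_circularity = mean(abs(r - rp$mu_r)),
    p7_radial_entropy = p7,
    p8_eccentricity = mask_eccentricity(mask)
  )
}

## Eccentricity of the second-moment-equivalent ellipse.
mask_eccentricity <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1] - mean(idx[, 1]); x <- idx[, 2] - mean(idx[, 2])
  mxx <- mean(x^2) + 1 / 12; myy <- mean(y^2) + 1 / 12; mxy <- mean(x * y)
  tr <- mxx + myy
  det_ <- sqrt((mxx - myy)^2 + 4 * mxy^2)
  l1 <- (tr + det_) / 2; l2 <- (tr - det_) / 2
  sqrt(max(0, 1 - l2 / l1))
}

#' Combined feature vector of a segmented lesion
#'
#' Binds the 13 direction-averaged texture features and the 8 morphological
#' descriptors into one row, the per-lesion record used by the classifier.
#'
#' @inheritParams texture_features
#' @inheritParams shape_features
#' @return A one-row tibble with 21 feature columns.
#' @export
lesion_features <- function(image, mask, levels = 64L, radial_bins = 10L) {
  dplyr::bind_cols(texture_features(image, mask, levels = levels),
                   shape_features(mask, radial_bins = radial_bins))
}
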
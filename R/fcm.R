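#' Fuzzy c-means parameters
#'
#' Defaults follow the published configuration for lesion ROIs: 2 clusters,
#' weighting exponent 2, stop criterion 0.0005 on the maximum membership
#' change, at most 100 iterations, and a likelihood threshold of 0.5 for
#' binarization. Cluster centers are initialized deterministically at the
#' 25th and 75th intensity percentiles of the ROI.
#'
#' @param n_clusters Number of clusters (fixed at 2 for lesion/background).
#' @param weighting_exponent Fuzzifier m (> 1).
#' @param stop_criterion Convergence threshold: maximum absolute change of
#'   any membership value between iterations.
#' @param max_iterations Iteration cap.
#' @param threshold Likelihood threshold T in (0, 1) for [binarize()].
#' @param seed Used only to break a tie if the initialization percentiles
#'   coincide.
#' @return A list of class `fcm_params`.
#' @export
fcm_params <- function(n_clusters = 2L, weighting_exponent = 2,
                       stop_criterion = 5e-4, max_iterations = 100L,
                       threshold = 0.5, seed = 1L) {
  stopifnot(weighting_exponent > 1, threshold > 0, threshold < 1,
            max_iterations >= 1, n_clusters == 2L)
  structure(list(n_clusters = 2L, weighting_exponent = weighting_exponent,
                 stop_criterion = stop_criterion,
                 max_iterations = as.integer(max_iterations),
                 threshold = threshold, seed = as.integer(seed)),
            class = "fcm_params")
}

#' Fuzzy c-means clustering of ROI intensities
#'
#' Runs standard fuzzy c-means on the scalar intensity values of an ROI and
#' returns the membership map of the brighter cluster (lesions are contrast
#' enhancing, so the lesion is always the cluster with the higher center —
#' cluster identity is by center intensity, never by index). The alternating
#' updates are the textbook ones: centers
#' \eqn{c_k = \sum u_{ik}^m x_i / \sum u_{ik}^m} and memberships
#' \eqn{u_{ik} = 1 / \sum_j (|x_i - c_k| / |x_i - c_j|)^{2/(m-1)}},
#' iterated until the largest membership change falls below
#' `params$stop_criterion` or `params$max_iterations` is reached. Because the
#' feature is scalar intensity, the update is computed once per distinct gray
#' level and broadcast to pixels, which is exactly equivalent to the
#' per-pixel iteration.
#'
#' @param roi_pixels Numeric matrix of ROI intensities.
#' @param params An [fcm_params()] object.
#' @return A numeric matrix in \[0, 1\]: per-pixel membership of the lesion
#'   (bright) cluster, with attributes `centers` (sorted ascending),
#'   `iterations`, and `objective` (the per-iteration objective
#'   \eqn{J_m = \sum_k \sum_i u_{ik}^m (x_i - c_k)^2}, non-increasing).
#' @export
fcm_cluster <- function(roi_pixels, params = fcm_params()) {
  assert_gray_image(roi_pixels)
  x <- as.vector(roi_pixels)
  vals <- sort(unique(x))
  if (length(vals) < 2L)
    stop("degenerate ROI: single intensity", call. = FALSE)
  counts <- tabulate(match(x, vals), length(vals))
  m <- params$weighting_exponent
  centers <- unname(stats::quantile(x, c(0.25, 0.75)))
  if (centers[1] == centers[2]) {
    # percentiles coincide (heavily skewed ROI); fall back to a seeded
    # symmetric split about the coincident value within the data range
    set.seed(params$seed)
    eps <- diff(range(x)) * stats::runif(1, 0.2, 0.3)
    centers <- centers + c(-eps, eps)
  }
  memb_from_centers <- function(centers) {
    d2 <- outer(vals, centers, function(v, c) (v - c)^2)
    pw <- d2^(-1 / (m - 1))          # Inf where a value equals a center
    u <- pw / rowSums(pw)
    hit <- !is.finite(pw)
    if (any(hit)) {
      rows <- which(rowSums(hit) > 0)
      u[rows, ] <- hit[rows, , drop = FALSE] / rowSums(hit[rows, , drop = FALSE])
    }
    u
  }
  u <- memb_from_centers(centers)
  objective <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- (u^m) * counts
    centers <- colSums(w * vals) / colSums(w)
    u_new <- memb_from_centers(centers)
    d2 <- outer(vals, centers, function(v, c) (v - c)^2)
    objective <- c(objective, sum((u_new^m) * counts * d2))
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < params$stop_criterion || iter >= params$max_iterations) break
  }
  bright <- which.max(centers)
  map <- matrix(u[match(x, vals), bright], nrow(roi_pixels), ncol(roi_pixels))
  attr(map, "centers") <- sort(centers)
  attr(map, "iterations") <- iter
  attr(map, "objective") <- objective
  map
}

#' Threshold a membership map into a binary mask
#'
#' Applies the likelihood threshold with a strict inequality: pixels with
#' membership exactly equal to `threshold` are excluded.
#'
#' @param membership Numeric matrix of lesion-cluster memberships in \[0, 1\].
#' @param threshold Likelihood threshold T in (0, 1).
#' @return Logical mask (`membership > threshold`).
#' @export
binarize <- function(membership, threshold = 0.5) {
  stopifnot(is.matrix(membership), threshold > 0, threshold < 1)
  membership > threshold
}

#' Morphological cleanup of a binary segmentation
#'
#' Applies, in order: hole filling (background components not connected to
#' the border, 4-connected background), morphological opening with a
#' radius-1 disk (3x3 cross) structuring element, and retention of the
#' largest 8-connected component, removing disconnected specks around the
#' main lesion.
#'
#' @param mask Logical matrix.
#' @return Cleaned logical mask.
#' @export
cleanup <- function(mask) {
  assert_mask(mask)
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  m <- EBImage::fillHull(m)
  m <- EBImage::opening(m, EBImage::makeBrush(3, "diamond"))
  if (!any(m > 0))
    stop("no lesion component survives cleanup", call. = FALSE)
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Rectangular region of interest
#'
#' 1-based inclusive pixel bounds `[top, bottom] x [left, right]` within the
#' image frame.
#'
#' @param top,left,bottom,right Integer pixel indices.
#' @return A list of class `roi_box`.
#' @export
roi_box <- function(top, left, bottom, right) {
  stopifnot(top >= 1, left >= 1, bottom >= top, right >= left)
  structure(list(top = as.integer(top), left = as.integer(left),
                 bottom = as.integer(bottom), right = as.integer(right)),
            class = "roi_box")
}

crop_roi <- function(image, roi) {
  stopifnot(inherits(roi, "roi_box"))
  if (roi$bottom > nrow(image) || roi$right > ncol(image))
    stop("ROI exceeds image bounds", call. = FALSE)
  image[roi$top:roi$bottom, roi$left:roi$right, drop = FALSE]
}

#' Initial lesion segmentation by fuzzy c-means
#'
#' The first segmentation step: crop the ROI, cluster its intensities with
#' [fcm_cluster()], threshold the bright-cluster membership map with
#' [binarize()], clean up with [cleanup()], and re-embed the ROI mask into
#' the full image frame. The result tends to sit slightly inside the true
#' lesion boundary; the GVF snake of [refine()] then expands it onto the
#' edge.
#'
#' @param image Full grayscale image matrix.
#' @param roi An [roi_box()] enclosing the lesion.
#' @param params An [fcm_params()] object.
#' @return Logical mask in the full image frame.
#' @examples
#' ph <- make_phantom(phantom_spec(noise_sigma = 0, seed = 2))
#' mask <- initial_segment(ph$image, roi_box(30, 30, 99, 99))
#' overlap(mask, ph$mask)$aor2
#' @export
initial_segment <- function(image, roi, params = fcm_params()) {
  assert_gray_image(image)
  sub <- crop_roi(image, roi)
  membership <- fcm_cluster(sub, params)
  mask_roi <- cleanup(binarize(membership, params$threshold))
  out <- matrix(FALSE, nrow(image), ncol(image))
  out[roi$top:roi$bottom, roi$left:roi$right] <- mask_roi
  out
}
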
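#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules. Images are plain numeric matrices
## indexed [row, col] with gray levels on 0..255; masks are logical matrices
## in the same frame. All indexing is 1-based and inclusive.

assert_gray_image <- function(image, min_dim = 2L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(image)))
    stop("image contains non-finite values", call. = FALSE)
  if (nrow(image) < min_dim || ncol(image) < min_dim)
    stop(sprintf("image must be at least %dx%d", min_dim, min_dim), call. = FALSE)
  invisible(image)
}

assert_mask <- function(mask, allow_empty = FALSE) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  if (!allow_empty && !any(mask))
    stop("mask is empty", call. = FALSE)
  invisible(mask)
}

## Replicate-padded separable Gaussian smoothing; kernel truncated at 4 sigma.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  smooth_1d <- function(m) {
    n <- nrow(m)
    idx <- outer(seq_len(n), -r:r, `+`)
    idx[idx < 1L] <- 1L
    idx[idx > n] <- n
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(smooth_1d(t(smooth_1d(x))))
}

## Central-difference gradients with replicated borders; returns d/dcol ("x",
## horizontal) and d/drow ("y", vertical) on unit pixel spacing.
image_gradient <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  ip <- c(2:nr, nr); im <- c(1, 1:(nr - 1))
  jp <- c(2:nc, nc); jm <- c(1, 1:(nc - 1))
  list(
    gx = (x[, jp, drop = FALSE] - x[, jm, drop = FALSE]) / 2,
    gy = (x[ip, , drop = FALSE] - x[im, , drop = FALSE]) / 2
  )
}

## 5-point Laplacian with replicated borders.
laplacian <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  ip <- c(2:nr, nr); im <- c(1, 1:(nr - 1))
  jp <- c(2:nc, nc); jm <- c(1, 1:(nc - 1))
  x[ip, , drop = FALSE] + x[im, , drop = FALSE] +
    x[, jp, drop = FALSE] + x[, jm, drop = FALSE] - 4 * x
}

## Ordered 8-connected boundary pixels of a single-component mask, as an
## n x 2 matrix of (row, col), traced with EBImage's Moore contour follower.
trace_boundary <- function(mask) {
  assert_mask(mask)
  lab <- EBImage::bwlabel(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  if (max(lab) != 1L)
    stop("mask must have exactly one connected component", call. = FALSE)
  oc <- EBImage::ocontour(lab)
  b <- oc[[1]] + 1L  # EBImage is 0-based; first matrix dim is our row
  colnames(b) <- c("row", "col")
  b
}

## Signed polygon area via the shoelace formula (positive = counterclockwise
## in (x=col, y=row) with row increasing downward is clockwise visually; we
## only use magnitude and sign consistency).
shoelace_area <- function(x, y) {
  n <- length(x)
  i2 <- c(2:n, 1)
  sum(x * y[i2] - x[i2] * y) / 2
}

## Deterministic child seed for item i of a run seeded with `seed`.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1009 + 7919 * as.double(i)) %% 2147483647)
}
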
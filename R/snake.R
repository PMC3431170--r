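#' Snake (active contour) parameters
#'
#' Defaults follow the published configuration: tension `alpha = 0.01`,
#' rigidity `beta = 0`. The remaining numerics are this package's choices:
#' semi-implicit time step `gamma = 1`, at most 400 iterations with
#' convergence declared when the mean point displacement of one iteration
#' falls below 0.01 px, and resampling to 1-px spacing every 10 iterations
#' to keep point density uniform as the curve grows or shrinks.
#'
#' @param alpha Tension weight (>= 0).
#' @param beta Rigidity weight (>= 0); 0 removes the fourth-order term.
#' @param gamma Viscosity/time-step parameter of the semi-implicit update.
#' @param max_iterations Iteration cap.
#' @param convergence_tol Mean per-point displacement (px) below which the
#'   snake is considered balanced.
#' @param resample_spacing Target arc-length spacing (px) when resampling.
#' @param resample_every Resample period in iterations.
#' @param normalize_force If `TRUE` (default), the external force is the
#'   saturated-normalized field \eqn{v / \max(|v|, s)}: unit vectors where
#'   the field is strong (fast, bounded steps through weak far-field
#'   regions) and linear below the floor `force_floor` (a stable
#'   equilibrium at the edge ridge, where the field changes sign). `FALSE`
#'   uses the raw field.
#' @param force_floor Saturation floor `s` for the normalization.
#' @return A list of class `snake_params`.
#' @export
snake_params <- function(alpha = 0.01, beta = 0, gamma = 1,
                         max_iterations = 400L, convergence_tol = 0.01,
                         resample_spacing = 1, resample_every = 10L,
                         normalize_force = TRUE, force_floor = 0.1) {
  stopifnot(alpha >= 0, beta >= 0, gamma > 0, max_iterations >= 1,
            convergence_tol >= 0, resample_spacing > 0, resample_every >= 1,
            force_floor > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 resample_spacing = resample_spacing,
                 resample_every = as.integer(resample_every),
                 normalize_force = isTRUE(normalize_force),
                 force_floor = force_floor),
            class = "snake_params")
}

## Resample a closed polygon to (approximately) uniform arc-length spacing.
resample_closed <- function(pts, spacing) {
  n <- nrow(pts)
  closed <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  keep <- seg > 1e-12
  if (!all(keep)) {            # drop coincident points
    closed <- closed[c(keep, TRUE), , drop = FALSE]
    seg <- seg[keep]
  }
  total <- sum(seg)
  m <- max(8L, round(total / spacing))
  s <- cumsum(c(0, seg))
  target <- total * (seq_len(m) - 1) / m
  x <- stats::approx(s, closed[, 1], xout = target)$y
  y <- stats::approx(s, closed[, 2], xout = target)$y
  cbind(x = x, y = y)
}

#' Extract a snake contour from a binary mask
#'
#' Traces the 8-connected boundary of a single-component mask in order,
#' orients it counterclockwise, and resamples it to uniform arc-length
#' spacing. Points are continuous (x = column, y = row) pixel-center
#' coordinates.
#'
#' @param mask Logical matrix with exactly one connected component.
#' @param spacing Target spacing between consecutive points, pixels.
#' @return An n x 2 matrix of class `snake_contour` with columns `x`, `y`;
#'   the curve is closed implicitly (last point connects to the first).
#' @export
mask_to_contour <- function(mask, spacing = 1) {
  b <- trace_boundary(mask)
  pts <- cbind(x = as.numeric(b[, "col"]), y = as.numeric(b[, "row"]))
  if (nrow(pts) < 4L) stop("contour too small", call. = FALSE)
  if (shoelace_area(pts[, 1], pts[, 2]) < 0) pts <- pts[rev(seq_len(nrow(pts))), ]
  structure(resample_closed(pts, spacing), class = "snake_contour")
}

## Bilinear interpolation of a matrix field at continuous (x=col, y=row)
## positions, clamped to the domain.
bilinear <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x <- pmin(pmax(x, 1), nc); y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  dx <- x - x0; dy <- y - y0
  m[cbind(y0, x0)] * (1 - dx) * (1 - dy) +
    m[cbind(y0, x0 + 1)] * dx * (1 - dy) +
    m[cbind(y0 + 1, x0)] * (1 - dx) * dy +
    m[cbind(y0 + 1, x0 + 1)] * dx * dy
}

## Pentadiagonal (circulant) internal-force stiffness matrix for n points:
## A x approximates -(alpha x'' - beta x'''') with periodic boundary.
snake_stiffness <- function(n, alpha, beta) {
  idx <- function(k) ((seq_len(n) - 1 + k) %% n) + 1
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- 2 * alpha + 6 * beta
  A[cbind(seq_len(n), idx(1))] <- A[cbind(seq_len(n), idx(-1))] <- -alpha - 4 * beta
  A[cbind(seq_len(n), idx(2))] <- A[cbind(seq_len(n), idx(-2))] <- beta
  A
}

#' Evolve a snake under internal and GVF external forces
#'
#' Iterates the semi-implicit update
#' \eqn{x_{t+1} = (A + \gamma I)^{-1} (\gamma x_t + F_{ext}(x_t))}, where
#' `A` is the periodic pentadiagonal stiffness matrix built from the tension
#' `alpha` and rigidity `beta`, and the external force is the GVF field
#' bilinearly interpolated at the snake points. The contour is resampled to
#' uniform spacing every `resample_every` iterations and evolution stops
#' when the mean displacement of an iteration drops below
#' `convergence_tol`, or at `max_iterations`.
#'
#' @param contour A `snake_contour` (see [mask_to_contour()]).
#' @param field A `gvf_field` (see [compute_gvf()]); pass a zero field to
#'   evolve under internal forces alone.
#' @param params A [snake_params()] object.
#' @return The evolved `snake_contour`, with attributes `iterations` and
#'   `mean_displacement` (per-iteration trace).
#' @export
evolve_snake <- function(contour, field, params = snake_params()) {
  stopifnot(inherits(contour, "snake_contour"), inherits(field, "gvf_field"))
  u <- field$u; v <- field$v
  if (params$normalize_force) {
    mag <- pmax(sqrt(u^2 + v^2), params$force_floor)
    u <- u / mag; v <- v / mag
  }
  pts <- unclass(contour)
  gamma <- params$gamma
  solver <- NULL; n_cached <- -1L
  disp <- numeric(0)
  for (it in seq_len(params$max_iterations)) {
    n <- nrow(pts)
    if (n < 8L) stop("snake collapsed", call. = FALSE)
    if (n != n_cached) {
      A <- snake_stiffness(n, params$alpha, params$beta)
      solver <- solve(A + gamma * diag(n))
      n_cached <- n
    }
    fx <- bilinear(u, pts[, 1], pts[, 2])
    fy <- bilinear(v, pts[, 1], pts[, 2])
    new_pts <- cbind(solver %*% (gamma * pts[, 1] + fx),
                     solver %*% (gamma * pts[, 2] + fy))
    d <- mean(sqrt(rowSums((new_pts - pts)^2)))
    disp <- c(disp, d)
    pts <- new_pts
    if (it %% params$resample_every == 0L)
      pts <- resample_closed(remove_loops(pts), params$resample_spacing)
    if (d < params$convergence_tol) break
  }
  colnames(pts) <- c("x", "y")
  structure(pts, class = "snake_contour",
            iterations = length(disp), mean_displacement = disp)
}

## Remove small self-intersection loops from a closed polygon: when two
## non-adjacent edges cross, the shorter arc between them is excised. Part
## of the snake's reparameterization, as in standard snake implementations.
remove_loops <- function(pts, max_passes = 10L) {
  for (pass in seq_len(max_passes)) {
    n <- nrow(pts)
    if (n < 8L) break
    hit <- find_first_crossing(pts)
    if (is.null(hit)) break
    i <- hit[1]; j <- hit[2]
    inner <- (i + 1L):j
    pts <- if (length(inner) <= n - length(inner))
      pts[-inner, , drop = FALSE]
    else pts[inner, , drop = FALSE]
  }
  pts
}

find_first_crossing <- function(pts) {
  n <- nrow(pts)
  p1 <- pts; p2 <- pts[c(2:n, 1), , drop = FALSE]
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]
    if (!length(js)) next
    d1 <- cross(p2[i, 1] - p1[i, 1], p2[i, 2] - p1[i, 2],
                p1[js, 1] - p1[i, 1], p1[js, 2] - p1[i, 2])
    d2 <- cross(p2[i, 1] - p1[i, 1], p2[i, 2] - p1[i, 2],
                p2[js, 1] - p1[i, 1], p2[js, 2] - p1[i, 2])
    d3 <- cross(p2[js, 1] - p1[js, 1], p2[js, 2] - p1[js, 2],
                p1[i, 1] - p1[js, 1], p1[i, 2] - p1[js, 2])
    d4 <- cross(p2[js, 1] - p1[js, 1], p2[js, 2] - p1[js, 2],
                p2[i, 1] - p1[js, 1], p2[i, 2] - p1[js, 2])
    bad <- which(d1 * d2 < 0 & d3 * d4 < 0)
    if (length(bad)) return(c(i, js[bad[1]]))
  }
  NULL
}

## TRUE if any two non-adjacent edges of the closed polygon properly cross.
contour_self_intersects <- function(pts) {
  n <- nrow(pts)
  p1 <- pts; p2 <- pts[c(2:n, 1), , drop = FALSE]
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]
    if (!length(js)) next
    d1 <- cross(p2[i, 1] - p1[i, 1], p2[i, 2] - p1[i, 2],
                p1[js, 1] - p1[i, 1], p1[js, 2] - p1[i, 2])
    d2 <- cross(p2[i, 1] - p1[i, 1], p2[i, 2] - p1[i, 2],
                p2[js, 1] - p1[i, 1], p2[js, 2] - p1[i, 2])
    d3 <- cross(p2[js, 1] - p1[js, 1], p2[js, 2] - p1[js, 2],
                p1[i, 1] - p1[js, 1], p1[i, 2] - p1[js, 2])
    d4 <- cross(p2[js, 1] - p1[js, 1], p2[js, 2] - p1[js, 2],
                p2[i, 1] - p1[js, 1], p2[i, 2] - p1[js, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

## Offset a closed CCW polygon outward along vertex normals. Used when a
## snake is initialized from a digital mask: the traced boundary runs
## through boundary-pixel centers, i.e. half a pixel inside the region
## boundary under the pixel-as-square model.
offset_outward <- function(pts, delta) {
  n <- nrow(pts)
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  tx <- pts[nxt, 1] - pts[prv, 1]
  ty <- pts[nxt, 2] - pts[prv, 2]
  len <- sqrt(tx^2 + ty^2)
  len[len < 1e-12] <- 1
  out <- cbind(x = pts[, 1] + delta * ty / len,
               y = pts[, 2] - delta * tx / len)
  structure(out, class = "snake_contour")
}

#' Rasterize a closed contour into a binary mask
#'
#' Marks pixels whose centers fall inside the polygon (even-odd rule);
#' centers lying exactly on the boundary count as inside, so a digital
#' boundary traced through pixel centers rasterizes back to the original
#' pixels. Errors on self-intersecting contours; warns and returns an
#' empty mask if the polygon contains no pixel center.
#'
#' @param contour A `snake_contour`.
#' @param shape Target mask dimensions `c(rows, cols)`.
#' @return Logical matrix of the given shape.
#' @export
contour_to_mask <- function(contour, shape) {
  stopifnot(inherits(contour, "snake_contour"), length(shape) == 2L)
  pts <- unclass(contour)
  if (contour_self_intersects(pts))
    stop("self-intersecting contour cannot be rasterized", call. = FALSE)
  mask <- matrix(FALSE, shape[1], shape[2])
  rows <- max(1L, floor(min(pts[, 2]))):min(shape[1], ceiling(max(pts[, 2])))
  cols <- max(1L, floor(min(pts[, 1]))):min(shape[2], ceiling(max(pts[, 1])))
  cx <- rep(cols, each = length(rows))
  cy <- rep(rows, times = length(cols))
  inside <- pracma::inpolygon(cx, cy, pts[, 1], pts[, 2], boundary = TRUE)
  mask[cbind(cy[inside], cx[inside])] <- TRUE
  if (!any(mask)) warning("contour contains no pixel center; empty mask")
  mask
}

#' Refine an initial segmentation with a GVF snake
#'
#' The second segmentation step: on the ROI bounding the initial mask
#' (padded by `margin` pixels), computes the edge map and GVF field,
#' initializes the snake on the initial mask boundary, evolves it to force
#' balance, and rasterizes the final contour back into the full image
#' frame.
#'
#' @param image Full grayscale image matrix.
#' @param initial_mask Non-empty logical mask (e.g. from
#'   [initial_segment()]).
#' @param gvf_params A [gvf_params()] object.
#' @param snake_params A [snake_params()] object.
#' @param presmooth_sigma Passed to [edge_map()].
#' @param margin ROI padding around the initial mask, pixels.
#' @return Logical mask in the full image frame, with the final full-frame
#'   `snake_contour` attached as attribute `contour`.
#' @examples
#' ph <- make_phantom(phantom_spec(noise_sigma = 0, seed = 2))
#' init <- initial_segment(ph$image, roi_box(30, 30, 99, 99))
#' refined <- refine(ph$image, init)
#' overlap(refined, ph$mask)$aor2
#' @export
refine <- function(image, initial_mask, gvf_params = lesionsnake::gvf_params(),
                   snake_params = lesionsnake::snake_params(),
                   presmooth_sigma = 1, margin = 10L) {
  assert_gray_image(image)
  assert_mask(initial_mask)
  rows <- range(which(rowSums(initial_mask) > 0))
  cols <- range(which(colSums(initial_mask) > 0))
  top <- max(1L, rows[1] - margin); bottom <- min(nrow(image), rows[2] + margin)
  left <- max(1L, cols[1] - margin); right <- min(ncol(image), cols[2] + margin)
  sub_img <- image[top:bottom, left:right, drop = FALSE]
  sub_mask <- initial_mask[top:bottom, left:right, drop = FALSE]
  f <- edge_map(sub_img, presmooth_sigma)
  # rescale the edge map to unit maximum so the GVF data term anchors the
  # diffusion regardless of absolute image contrast (standard practice)
  if (max(f) > 0) f <- f / max(f)
  field <- compute_gvf(f, gvf_params)
  contour <- mask_to_contour(sub_mask, snake_params$resample_spacing)
  # the traced digital boundary lies half a pixel inside the region edge
  contour <- offset_outward(unclass(contour), 0.5)
  evolved <- evolve_snake(contour, field, snake_params)
  evolved <- structure(remove_loops(unclass(evolved)), class = "snake_contour")
  sub_out <- contour_to_mask(evolved, dim(sub_img))
  out <- matrix(FALSE, nrow(image), ncol(image))
  out[top:bottom, left:right] <- sub_out
  full_contour <- unclass(evolved)
  full_contour[, 1] <- full_contour[, 1] + (left - 1)
  full_contour[, 2] <- full_contour[, 2] + (top - 1)
  attr(out, "contour") <- structure(full_contour, class = "snake_contour")
  out
}
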
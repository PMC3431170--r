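#' Specification of a synthetic lesion phantom
#'
#' Describes one mass-like lesion on a darker, noisy background. The lesion
#' boundary is the star polygon \eqn{r(\theta) = R (1 + A \cos(k\theta))}
#' with base radius \eqn{R}, spicule amplitude \eqn{A} and \eqn{k} spicules:
#' \eqn{A = 0} gives a smooth disk-like ("benign") outline, large \eqn{A}
#' with many spicules a star-like ("malignant") outline. Within-lesion
#' texture heterogeneity is a smoothed multiplicative Gaussian field, so the
#' two classes can also differ in co-occurrence texture, not just shape.
#'
#' @param image_size Integer vector (rows, cols); a scalar is recycled.
#' @param lesion_class `"benign"` or `"malignant"` (label only; geometry is
#'   governed by the numeric fields).
#' @param center Lesion center (row, col) in pixels; default image center.
#' @param base_radius Base radius \eqn{R} in pixels.
#' @param n_spicules Number of spicules \eqn{k} (0 disables modulation).
#' @param spicule_amplitude Amplitude \eqn{A} as a fraction of `base_radius`.
#' @param lesion_intensity,background_intensity Gray levels in \[0, 255\];
#'   the lesion must be brighter than the background (contrast enhancement).
#' @param texture_heterogeneity Standard deviation (gray levels) of the
#'   smoothed multiplicative intensity modulation inside the lesion.
#' @param rim_falloff Fraction by which enhancement fades from the lesion
#'   core to its margin (quadratic radial profile). Contrast enhancement of
#'   mass lesions is strongest in the core and weaker at the rim, which is
#'   what makes an intensity-only clustering cut slightly inside the true
#'   margin; 0 gives a flat lesion.
#' @param parenchyma_sd Strength (gray levels) of patchy background
#'   enhancement outside the lesion (half-normal smooth patches emulating
#'   enhancing fibroglandular tissue), ramped in over the 4 px closest to
#'   the lesion margin so the mass margin itself stays visible. Raises the
#'   background cluster's intensity spread, one of the things that makes
#'   intensity-only clustering imperfect on real ROIs; 0 disables.
#' @param blur_sigma Gaussian blur applied to the ideal image, pixels.
#' @param noise_sigma Additive Gaussian noise, gray levels.
#' @param seed Integer RNG seed; identical specs give bit-identical phantoms.
#' @return An object of class `phantom_spec` (a validated list).
#' @export
phantom_spec <- function(image_size = c(128L, 128L),
                         lesion_class = c("benign", "malignant"),
                         center = NULL,
                         base_radius = 18,
                         n_spicules = 0L,
                         spicule_amplitude = 0,
                         lesion_intensity = 180,
                         background_intensity = 60,
                         texture_heterogeneity = 0,
                         rim_falloff = 0.4,
                         parenchyma_sd = 0,
                         blur_sigma = 1,
                         noise_sigma = 5,
                         seed = 1L) {
  lesion_class <- match.arg(lesion_class)
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  image_size <- as.integer(image_size)
  if (is.null(center)) center <- (image_size + 1) / 2
  if (lesion_intensity <= background_intensity)
    stop("lesion_intensity must exceed background_intensity", call. = FALSE)
  if (base_radius <= 2)
    stop("base_radius must exceed 2 pixels", call. = FALSE)
  if (spicule_amplitude < 0 || spicule_amplitude >= 1)
    stop("spicule_amplitude must lie in [0, 1)", call. = FALSE)
  if (rim_falloff < 0 || rim_falloff >= 1)
    stop("rim_falloff must lie in [0, 1)", call. = FALSE)
  if (parenchyma_sd < 0)
    stop("parenchyma_sd must be non-negative", call. = FALSE)
  r_max <- base_radius * (1 + spicule_amplitude)
  lo <- center - r_max
  hi <- center + r_max
  if (any(lo < 1) || any(hi > image_size))
    stop(sprintf(
      "lesion leaves the frame: needs rows %.1f..%.1f, cols %.1f..%.1f inside 1..%d x 1..%d",
      lo[1], hi[1], lo[2], hi[2], image_size[1], image_size[2]), call. = FALSE)
  structure(list(
    image_size = image_size, lesion_class = lesion_class,
    center = as.numeric(center), base_radius = base_radius,
    n_spicules = as.integer(n_spicules), spicule_amplitude = spicule_amplitude,
    lesion_intensity = lesion_intensity,
    background_intensity = background_intensity,
    texture_heterogeneity = texture_heterogeneity,
    rim_falloff = rim_falloff, parenchyma_sd = parenchyma_sd,
    blur_sigma = blur_sigma, noise_sigma = noise_sigma,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

## Exact rasterization of the star-polygon interior: a pixel center is inside
## iff its polar radius about the lesion center is <= r(theta). The family is
## radially star-shaped, so this test is the exact ground truth.
rasterize_star <- function(spec) {
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dy <- rows - spec$center[1]
  dx <- cols - spec$center[2]
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  rb <- spec$base_radius *
    (1 + spicule_term(spec$spicule_amplitude, spec$n_spicules, theta))
  mask <- rho <= rb
  # normalized radial position inside the lesion, for the rim profile, and
  # signed distance beyond the boundary, for the peritumoral clearance ramp
  attr(mask, "radial_frac") <- pmin(rho / rb, 1)
  attr(mask, "outside_dist") <- pmax(rho - rb, 0)
  mask
}

spicule_term <- function(amplitude, k, theta) {
  if (amplitude <= 0 || k == 0L) return(0)
  amplitude * cos(k * theta)
}

#' Generate a synthetic lesion phantom
#'
#' Rasterizes the star-polygon lesion of a [phantom_spec()], records the
#' exact ground-truth mask, then builds the 8-bit image: flat background,
#' brighter lesion optionally modulated by a smoothed multiplicative texture
#' field, Gaussian boundary blur, additive Gaussian noise, clipping to
#' \[0, 255\] and rounding to integer gray levels. The stored mask comes from
#' the noiseless rasterization and is never affected by blur or noise.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `image` (numeric matrix, integer gray levels
#'   0-255), `mask` (logical ground-truth matrix), `label` (lesion class) and
#'   `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(seed = 7))
#' range(ph$image)
#' sum(ph$mask)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  mask <- rasterize_star(spec)
  radial_frac <- attr(mask, "radial_frac")
  outside_dist <- attr(mask, "outside_dist")
  attr(mask, "radial_frac") <- NULL
  attr(mask, "outside_dist") <- NULL
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  img <- matrix(spec$background_intensity, spec$image_size[1], spec$image_size[2])
  amp <- spec$lesion_intensity - spec$background_intensity
  img[mask] <- spec$background_intensity +
    amp * (1 - spec$rim_falloff * radial_frac[mask]^2)
  if (spec$parenchyma_sd > 0) {
    pf <- matrix(stats::rnorm(length(img)), nrow(img), ncol(img))
    pf <- gaussian_smooth(pf, 5)
    pf <- pf / stats::sd(pf)
    ramp <- pmin(outside_dist / 4, 1)   # clearance ramp at the margin
    img <- img + spec$parenchyma_sd * pmax(pf, 0) * ramp
  }
  if (spec$texture_heterogeneity > 0) {
    field <- matrix(stats::rnorm(length(img)), nrow(img), ncol(img))
    field <- gaussian_smooth(field, 4)  # coarse, enhancement-like patchiness
    field <- field / stats::sd(field)  # unit-sd smooth field
    img[mask] <- img[mask] + spec$texture_heterogeneity * field[mask]
  }
  if (spec$blur_sigma > 0) img <- gaussian_smooth(img, spec$blur_sigma)
  if (spec$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(length(img), sd = spec$noise_sigma),
                        nrow(img), ncol(img))
  img <- round(pmin(pmax(img, 0), 255))
  list(image = img, mask = mask, label = spec$lesion_class, spec = spec)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Default per-class phantom parameter distributions
#'
#' Returns the sampling distributions used by [make_cohort()] for each class.
#' Benign lesions are smooth (spicule amplitude below 0.05) and texturally
#' homogeneous; malignant lesions carry 6-12 spicules of amplitude 0.2-0.35,
#' higher enhancement and stronger heterogeneity — emulating the smooth/
#' homogeneous versus spiculated/heterogeneous contrast seen clinically.
#' `signal` restricts the class difference to one feature family: with
#' `"morphology"` both classes share intensity and heterogeneity, with
#' `"texture"` both are smooth disks, and with `"none"` the distributions
#' are identical (a no-signal null).
#'
#' Each class entry is a list of functions; each function takes no arguments
#' and draws one value (the cohort generator seeds the RNG).
#'
#' @param signal Which feature family separates the classes.
#' @return A list with entries `benign` and `malignant`.
#' @export
cohort_params <- function(signal = c("both", "morphology", "texture", "none")) {
  signal <- match.arg(signal)
  benign <- list(
    base_radius = function() stats::runif(1, 14, 22),
    n_spicules = function() sample(5:8, 1),
    spicule_amplitude = function() stats::runif(1, 0, 0.04),
    lesion_intensity = function() stats::runif(1, 160, 180),
    texture_heterogeneity = function() stats::runif(1, 2, 6),
    rim_falloff = function() stats::runif(1, 0.3, 0.5),
    parenchyma_sd = function() 0,
    blur_sigma = function() 1.2,
    noise_sigma = function() 25
  )
  malignant <- benign
  if (signal %in% c("both", "morphology")) {
    malignant$n_spicules <- function() sample(6:9, 1)
    malignant$spicule_amplitude <- function() stats::runif(1, 0.07, 0.12)
  }
  if (signal %in% c("both", "texture")) {
    malignant$lesion_intensity <- function() stats::runif(1, 185, 210)
    malignant$texture_heterogeneity <- function() stats::runif(1, 14, 22)
  }
  list(benign = benign, malignant = malignant)
}

#' Generate a labeled cohort of lesion phantoms
#'
#' Draws per-lesion parameters from class-specific distributions and builds
#' each phantom with [make_phantom()]. All randomness descends from `seed`
#' through one deterministic child seed per phantom, so cohorts are exactly
#' reproducible and individual phantoms can be regenerated in isolation.
#'
#' @param n_benign,n_malignant Number of lesions per class (each >= 1).
#' @param class_params Per-class parameter distributions, as returned by
#'   [cohort_params()].
#' @param seed Integer master seed.
#' @param image_size Passed to [phantom_spec()].
#' @return A list of phantoms (see [make_phantom()]); benign lesions first.
#' @examples
#' cohort <- make_cohort(3, 3, seed = 1)
#' table(vapply(cohort, `[[`, "", "label"))
#' @export
make_cohort <- function(n_benign, n_malignant,
                        class_params = cohort_params(),
                        seed = 1L, image_size = c(128L, 128L)) {
  if (n_benign < 1 || n_malignant < 1)
    stop("both class counts must be >= 1", call. = FALSE)
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  purrr::map(seq_along(labels), function(i) {
    cls <- labels[i]
    set.seed(child_seed(seed, i))
    draws <- purrr::map(class_params[[cls]], function(f) f())
    spec <- phantom_spec(
      image_size = image_size, lesion_class = cls,
      base_radius = draws$base_radius, n_spicules = draws$n_spicules,
      spicule_amplitude = draws$spicule_amplitude,
      lesion_intensity = draws$lesion_intensity,
      texture_heterogeneity = draws$texture_heterogeneity,
      rim_falloff = draws$rim_falloff,
      parenchyma_sd = draws$parenchyma_sd,
      blur_sigma = draws$blur_sigma, noise_sigma = draws$noise_sigma,
      seed = child_seed(seed, 100000L + i)
    )
    make_phantom(spec)
  })
}
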
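# Independent oracles, written deliberately as literal textbook formulas
# (scalar loops, no vectorization) so they share no code path with the
# package implementations they check.

# Textbook fuzzy c-means on a vector of values: per-point loops, explicit
# membership and center updates. Same deterministic initialization contract
# as the package (centers given explicitly).
fcm_oracle <- function(x, centers, m = 2, tol = 5e-4, max_iter = 100L) {
  n <- length(x)
  k <- length(centers)
  u <- matrix(0, n, k)
  update_u <- function(centers) {
    for (i in seq_len(n)) {
      d <- abs(x[i] - centers)
      if (any(d == 0)) {
        u[i, ] <- as.numeric(d == 0) / sum(d == 0)
      } else {
        for (c1 in seq_len(k)) {
          s <- 0
          for (c2 in seq_len(k)) s <- s + (d[c1] / d[c2])^(2 / (m - 1))
          u[i, c1] <- 1 / s
        }
      }
    }
    u
  }
  u <- update_u(centers)
  for (it in seq_len(max_iter)) {
    for (c1 in seq_len(k)) {
      num <- 0; den <- 0
      for (i in seq_len(n)) {
        w <- u[i, c1]^m
        num <- num + w * x[i]
        den <- den + w
      }
      centers[c1] <- num / den
    }
    u_new <- update_u(centers)
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) break
  }
  list(u = u, centers = centers, iterations = it)
}

# Literal double-loop Haralick measures of one normalized GLCM.
haralick_oracle <- function(p) {
  G <- nrow(p)
  xlog <- function(v) if (v > 0) v * log(v) else 0
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((1:G) * px); muy <- sum((1:G) * py)
  sx <- sqrt(sum((1:G - mux)^2 * px)); sy <- sqrt(sum((1:G - muy)^2 * py))
  psum <- numeric(2 * G); pdif <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  asm <- 0; contrast <- 0; corr_num <- 0; idm <- 0; ent <- 0
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:G) for (j in 1:G) {
    asm <- asm + p[i, j]^2
    contrast <- contrast + (i - j)^2 * p[i, j]
    corr_num <- corr_num + i * j * p[i, j]
    idm <- idm + p[i, j] / (1 + (i - j)^2)
    ent <- ent - xlog(p[i, j])
    if (px[i] * py[j] > 0) {
      hxy1 <- hxy1 - p[i, j] * log(px[i] * py[j])
      hxy2 <- hxy2 - px[i] * py[j] * log(px[i] * py[j])
    }
  }
  sa <- 0; for (k in 2:(2 * G)) sa <- sa + k * psum[k]
  sv <- 0; for (k in 2:(2 * G)) sv <- sv + (k - sa)^2 * psum[k]
  se <- 0; for (k in 2:(2 * G)) se <- se - xlog(psum[k])
  da <- 0; for (k in 0:(G - 1)) da <- da + k * pdif[k + 1]
  dv <- 0; for (k in 0:(G - 1)) dv <- dv + (k - da)^2 * pdif[k + 1]
  de <- 0; for (k in 0:(G - 1)) de <- de - xlog(pdif[k + 1])
  hx <- 0; for (i in 1:G) hx <- hx - xlog(px[i])
  hy <- 0; for (j in 1:G) hy <- hy - xlog(py[j])
  c(angular_second_moment = asm,
    contrast = contrast,
    correlation = if (sx > 0 && sy > 0) (corr_num - mux * muy) / (sx * sy) else 0,
    inverse_difference_moment = idm,
    sum_average = sa, sum_variance = sv, sum_entropy = se,
    entropy = ent, difference_average = da, difference_variance = dv,
    difference_entropy = de,
    info_measure_corr_1 = if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0,
    info_measure_corr_2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - ent)))))
}

# Brute-force Mann-Whitney AUC: count positive/negative pairs, ties 0.5.
auc_pair_oracle <- function(scores, labels, positive = "malignant") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (if (a > b) 1 else if (a == b) 0.5 else 0)
  total / (length(pos) * length(neg))
}

# Closed-form Pearson r and paired t-test p-value.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
paired_t_oracle <- function(x, y) {
  d <- x - y
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  2 * pt(-abs(tstat), df = n - 1)
}

# Discrete disk mask.
disk_mask <- function(radius, size = 2 * radius + 11) {
  ctr <- (size + 1) / 2
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  sqrt((rows - ctr)^2 + (cols - ctr)^2) <= radius
}

# Star-polygon truth mask without image machinery.
star_mask <- function(radius, amplitude, k, size = 128) {
  make_phantom(phantom_spec(image_size = size, base_radius = radius,
                            n_spicules = k, spicule_amplitude = amplitude,
                            lesion_class = if (amplitude > 0.05) "malignant" else "benign",
                            noise_sigma = 0, blur_sigma = 0, seed = 1))$mask
}

# Truth-mask feature table for a cohort (fast path for classifier tests:
# no segmentation involved).
truth_features <- function(cohort) {
  dplyr::bind_cols(
    tibble::tibble(label = vapply(cohort, `[[`, "", "label")),
    dplyr::bind_rows(lapply(cohort, function(it)
      lesion_features(it$image, it$mask))))
}
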
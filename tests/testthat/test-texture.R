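test_that("a constant region concentrates all co-occurrence mass on one entry", {
  img <- matrix(120, 8, 8)
  mask <- matrix(TRUE, 8, 8)
  g <- compute_glcm(img, mask, levels = 8, theta = 0)
  expect_equal(sum(g), 1)
  expect_equal(unname(g[1, 1]), 1)
  feats <- texture_features(img, mask, levels = 8)
  expect_equal(feats$angular_second_moment, 1)
  expect_equal(feats$entropy, 0)
  expect_equal(feats$contrast, 0)
  expect_equal(feats$inverse_difference_moment, 1)
})

test_that("a two-level alternating strip gives the hand-counted co-occurrence", {
  img <- matrix(c(0, 1, 0, 1), 1, 4) * 255
  img <- rbind(img, img)  # 2 rows so the matrix is a valid image
  mask <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                 2, 4, byrow = TRUE)
  g <- compute_glcm(img, mask, levels = 2, theta = 0)
  # 3 ordered pairs (0,1),(1,0),(0,1) counted symmetrically -> all mass off-diagonal
  expect_equal(unname(g[1, 2]), 0.5)
  expect_equal(unname(g[2, 1]), 0.5)
  expect_equal(unname(g[1, 1]) + unname(g[2, 2]), 0)
})

test_that("a checkerboard has unit contrast along rows", {
  img <- 255 * outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  g <- compute_glcm(img, NULL, levels = 2, theta = 0)
  feats <- haralick_features(list(g))
  expect_equal(feats$contrast, 1)
})

test_that("all 13 direction-averaged measures match the literal-formula oracle", {
  set.seed(42)
  img <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
  mask <- matrix(TRUE, 16, 16)
  mask[1:3, 1:5] <- FALSE   # irregular mask region
  glcms <- lapply(c(0, 45, 90, 135), function(th)
    compute_glcm(img, mask, levels = 16, theta = th))
  got <- haralick_features(glcms)
  want <- Reduce(`+`, lapply(glcms, haralick_oracle)) / 4
  for (nm in names(want))
    expect_equal(got[[nm]], unname(want[nm]), tolerance = 1e-10, label = nm)
})

test_that("GLCMs are symmetric probability matrices for arbitrary inputs", {
  set.seed(3)
  for (i in 1:5) {
    img <- matrix(runif(400, 0, 255), 20, 20)
    mask <- matrix(runif(400) > 0.3, 20, 20)
    th <- sample(c(0, 45, 90, 135), 1)
    g <- compute_glcm(img, mask, levels = 12, theta = th)
    expect_equal(sum(g), 1, tolerance = 1e-12)
    expect_equal(unclass(g), t(unclass(g)), tolerance = 1e-12)
    expect_true(all(g >= 0))
  }
})

test_that("rotating the image by 90 degrees leaves the averaged features unchanged", {
  set.seed(9)
  img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  mask <- disk_mask(7, 20)
  rot <- function(m) t(m)[, nrow(m):1]   # 90-degree rotation
  f1 <- texture_features(img, mask, levels = 16)
  f2 <- texture_features(rot(img), rot(mask), levels = 16)
  expect_equal(as.numeric(f1), as.numeric(f2), tolerance = 1e-10)
})

test_that("entropy rises and uniformity falls with increasing heterogeneity", {
  mask <- matrix(TRUE, 24, 24)
  set.seed(5)
  hets <- c(0, 10, 25, 45, 80)
  ent <- asm <- numeric(length(hets))
  for (i in seq_along(hets)) {
    img <- 120 + matrix(rnorm(576, sd = hets[i] + 1e-9), 24, 24)
    img <- round(pmin(pmax(img, 0), 255))
    f <- texture_features(img, mask, levels = 16)
    ent[i] <- f$entropy; asm[i] <- f$angular_second_moment
  }
  expect_gt(ent[5], ent[1])
  expect_lt(cor(ent, asm, method = "spearman"), 0)
})

test_that("a mask too small to form pairs is rejected", {
  img <- matrix(1:100, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[5, 5] <- TRUE
  expect_error(compute_glcm(img, mask, levels = 4, theta = 0),
               "insufficient pairs")
})
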
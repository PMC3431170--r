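test_that("radial profile of a disk is flat and centered", {
  disk <- disk_mask(20)
  rp <- radial_profile(disk)
  expect_true(all(rp$r >= 19 & rp$r <= 21))
  ctr <- (dim(disk) + 1) / 2
  expect_lt(max(abs(rp$center - ctr)), 0.5)
  expect_equal(rp$mu_r, mean(rp$r))
})

test_that("degenerate masks are rejected", {
  single <- matrix(FALSE, 10, 10); single[5, 5] <- TRUE
  expect_error(radial_profile(single), "too small")
  two <- matrix(FALSE, 20, 20); two[2:6, 2:6] <- TRUE; two[12:16, 12:16] <- TRUE
  expect_error(radial_profile(two), "one connected component")
})

test_that("a large disk attains the analytic circle values", {
  f <- shape_features(disk_mask(20))
  expect_lt(abs(f$p1_compactness - 1), 0.15)
  expect_lt(f$p2_spiculation, 0.5)
  expect_gt(f$p4_elongation, 0.95)
  expect_gt(f$p5_solidity, 0.95)
  expect_lt(f$p6_circularity, 0.5)
  expect_lt(f$p7_radial_entropy, 0.35)
  expect_lt(f$p8_eccentricity, 0.2)
})

test_that("an axis-aligned rectangle satisfies the box identities", {
  rect <- matrix(FALSE, 50, 60)
  rect[11:30, 11:50] <- TRUE   # 20 x 40
  f <- shape_features(rect)
  expect_equal(f$p3_extent, 1)
  expect_equal(f$p4_elongation, 0.5)
  expect_equal(f$p5_solidity, 1, tolerance = 1e-10)
})

test_that("spiculation raises irregularity measures and lowers solidity", {
  smooth <- shape_features(star_mask(16, 0, 0L))
  spiky <- shape_features(star_mask(16, 0.3, 8L))
  expect_gt(spiky$p2_spiculation, smooth$p2_spiculation)
  expect_gt(spiky$p1_compactness, smooth$p1_compactness)
  expect_gt(spiky$p7_radial_entropy, smooth$p7_radial_entropy)
  expect_lt(spiky$p5_solidity, smooth$p5_solidity)
})

test_that("90-degree rotation leaves every descriptor unchanged", {
  m <- star_mask(15, 0.25, 7L)
  rot <- t(m)[, nrow(m):1]
  f1 <- shape_features(m); f2 <- shape_features(rot)
  expect_equal(as.numeric(f1), as.numeric(f2), tolerance = 1e-6)
})

test_that("scale behavior: ratios invariant, radial measures linear in size", {
  m <- star_mask(12, 0.2, 6L, size = 64)
  up <- m[rep(seq_len(64), each = 2), rep(seq_len(64), each = 2)]
  f1 <- shape_features(m); f2 <- shape_features(up)
  for (nm in c("p3_extent", "p4_elongation", "p5_solidity", "p8_eccentricity"))
    expect_lt(abs(f2[[nm]] - f1[[nm]]) / max(f1[[nm]], 1e-9), 0.05)
  expect_gt(f2$p6_circularity / f1$p6_circularity, 1.5)  # ~ doubles

  # compactness is scale-stable across natively rasterized sizes (block
  # upscaling is excluded: it turns diagonal chain steps into staircases
  # and inflates any chain-code perimeter by up to sqrt(2))
  fd10 <- shape_features(disk_mask(10))
  fd25 <- shape_features(disk_mask(25))
  expect_lt(abs(fd25$p1_compactness - fd10$p1_compactness) / fd10$p1_compactness,
            0.1)
})

test_that("eccentricity separates elongated from round regions", {
  rect <- matrix(FALSE, 50, 60); rect[21:28, 6:55] <- TRUE  # 8 x 50
  expect_gt(lesionsnake:::mask_eccentricity(rect), 0.95)
  expect_lt(lesionsnake:::mask_eccentricity(disk_mask(15)), 0.1)
})
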
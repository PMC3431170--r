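test_that("two-point data reach the exact fixed point with symmetric midpoint", {
  roi <- matrix(rep(c(50, 200), each = 32), 8, 8)
  m <- fcm_cluster(roi)
  expect_equal(unname(attr(m, "centers")), c(50, 200), tolerance = 1e-6)
  expect_true(all(abs(m[roi == 200] - 1) < 1e-3))
  expect_true(all(abs(m[roi == 50] - 0) < 1e-3))
  # a pixel exactly midway between the converged centers has membership 1/2
  roi2 <- matrix(c(rep(c(50, 200), each = 31), 125, 125), 8, 8)
  m2 <- fcm_cluster(roi2)
  expect_equal(m2[roi2 == 125][1], 0.5, tolerance = 1e-3)
})

test_that("membership maps match a textbook per-pixel oracle to 1e-6", {
  set.seed(7)
  ph <- make_phantom(phantom_spec(image_size = 64, base_radius = 10,
                                  noise_sigma = 10, seed = 7))
  roi <- ph$image[17:48, 17:48]
  m <- fcm_cluster(roi)
  centers0 <- unname(quantile(as.vector(roi), c(0.25, 0.75)))
  ora <- fcm_oracle(as.vector(roi), centers0)
  bright <- which.max(ora$centers)
  expect_lt(max(abs(as.vector(m) - ora$u[, bright])), 1e-6)
  expect_equal(sort(unname(attr(m, "centers"))), sort(ora$centers), tolerance = 1e-6)
})

test_that("the fuzzy objective is non-increasing and memberships stay normalized", {
  set.seed(8)
  roi <- matrix(runif(900, 0, 255), 30, 30)
  m <- fcm_cluster(roi)
  obj <- attr(m, "objective")
  expect_true(all(diff(obj) <= 1e-8))
  expect_true(all(m >= 0 & m <= 1))
  # two-cluster memberships are complementary: bright + dark = 1 by the
  # update formula, so the returned bright map must lie in [0,1] and the
  # implied dark map too
  expect_true(all(1 - m >= -1e-12))
})

test_that("cluster relabeling cannot flip the lesion: bright cluster is by center", {
  # reversed intensity ordering of the same data gives the mirrored map
  roi <- matrix(c(rep(40, 40), rep(210, 24)), 8, 8)
  m <- fcm_cluster(roi)
  expect_true(mean(m[roi == 210]) > 0.99)
  expect_true(mean(m[roi == 40]) < 0.01)
})

test_that("constant ROI is rejected as degenerate", {
  expect_error(fcm_cluster(matrix(7, 5, 5)), "degenerate ROI")
})

test_that("binarization uses a strict threshold and preserves counts", {
  m <- matrix(0.9, 4, 4)
  expect_true(all(binarize(m, 0.5)))
  expect_false(any(binarize(matrix(0.5, 4, 4), 0.5)))
  set.seed(1)
  m2 <- matrix(runif(100), 10, 10)
  expect_equal(sum(binarize(m2, 0.5)), sum(m2 > 0.5))
})

test_that("cleanup fills holes, drops specks and severs diagonal bridges", {
  hole <- matrix(FALSE, 14, 14); hole[3:12, 3:12] <- TRUE; hole[7, 7] <- FALSE
  filled <- cleanup(hole)
  expect_true(filled[7, 7])                    # interior hole filled
  expect_equal(sum(filled), 96)                # opening shaves the 4 corners

  speck <- matrix(FALSE, 30, 30)
  speck[5:18, 5:18] <- TRUE          # area 196
  speck[25:26, 25:26] <- TRUE        # distant speck
  out <- cleanup(speck)
  expect_equal(sum(out), 192)                  # 14x14 blob minus 4 corners
  expect_false(any(out[25:26, 25:26]))

  # blob joined to a speck through one diagonal pixel; opening severs it
  bridge <- matrix(FALSE, 30, 30)
  bridge[5:16, 5:16] <- TRUE
  bridge[17, 17] <- TRUE
  bridge[18:20, 18:20] <- TRUE
  out2 <- cleanup(bridge)
  lab <- EBImage::bwlabel(matrix(as.integer(out2), 30, 30))
  expect_equal(max(lab), 1)
  expect_false(any(out2[18:20, 18:20]))
})

test_that("initial segmentation recovers a clean phantom and re-embeds at the ROI", {
  ph <- make_phantom(phantom_spec(noise_sigma = 0, seed = 2))
  mask <- initial_segment(ph$image, roi_box(30, 30, 99, 99))
  expect_equal(dim(mask), dim(ph$image))
  expect_gt(overlap(mask, ph$mask)$aor2, 0.8)

  # shifting the ROI box around the same lesion yields the same mask
  mask2 <- initial_segment(ph$image, roi_box(25, 28, 105, 102))
  expect_gt(overlap(mask, mask2)$aor2, 0.95)
})

test_that("an ROI fully inside the lesion fails loudly, not silently", {
  ph <- make_phantom(phantom_spec(noise_sigma = 0, blur_sigma = 0,
                                  texture_heterogeneity = 0, rim_falloff = 0,
                                  seed = 2))
  # interior of the flat lesion is constant -> degenerate ROI error
  expect_error(initial_segment(ph$image, roi_box(60, 60, 70, 70)),
               "degenerate ROI")
})
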
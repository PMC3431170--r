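zero_field <- function(n) structure(list(u = matrix(0, n, n), v = matrix(0, n, n)),
                                    class = "gvf_field")

circle_contour <- function(cx, cy, r, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  structure(cbind(x = cx + r * cos(th), y = cy + r * sin(th)),
            class = "snake_contour")
}

test_that("mask boundaries become closed, uniformly spaced contours", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  ct <- mask_to_contour(sq)
  per <- sum(sqrt(rowSums((ct[c(2:nrow(ct), 1), ] - ct)^2)))
  expect_lt(abs(per - 36), 1)
  d <- sqrt(rowSums((ct[c(2:nrow(ct), 1), ] - ct)^2))
  expect_lt(max(d) / min(d), 1.1)

  disk <- disk_mask(20)
  ctd <- mask_to_contour(disk)
  area <- abs(lesionsnake:::shoelace_area(ctd[, 1], ctd[, 2]))
  expect_lt(abs(area - sum(disk)) / sum(disk), 0.05)
})

test_that("multi-component masks are rejected", {
  two <- matrix(FALSE, 20, 20)
  two[2:5, 2:5] <- TRUE; two[12:15, 12:15] <- TRUE
  expect_error(mask_to_contour(two), "one connected component")
})

test_that("with zero external field the tension term shrinks the perimeter monotonically", {
  ct <- circle_contour(25, 25, 15, 80)
  perim <- function(p) sum(sqrt(rowSums((p[c(2:nrow(p), 1), , drop = FALSE] - p)^2)))
  p_prev <- perim(ct)
  cur <- ct
  for (i in 1:20) {
    cur <- evolve_snake(cur, zero_field(50),
                        snake_params(max_iterations = 1, convergence_tol = 0,
                                     resample_every = 1000L))
    p_now <- perim(unclass(cur))
    expect_lt(p_now, p_prev)
    p_prev <- p_now
  }
})

test_that("rigidity zero removes the fourth-order block exactly", {
  A0 <- lesionsnake:::snake_stiffness(12, alpha = 0.01, beta = 0)
  A2 <- matrix(0, 12, 12)
  idx <- function(k) ((seq_len(12) - 1 + k) %% 12) + 1
  A2[cbind(1:12, 1:12)] <- 2 * 0.01
  A2[cbind(1:12, idx(1))] <- A2[cbind(1:12, idx(-1))] <- -0.01
  expect_identical(A0, A2)
})

test_that("the snake locks onto a high-contrast disk edge within a pixel", {
  ph <- make_phantom(phantom_spec(base_radius = 18, rim_falloff = 0,
                                  noise_sigma = 0, blur_sigma = 0, seed = 2))
  f <- edge_map(ph$image)
  f <- f / max(f)
  g <- compute_gvf(f)
  ct <- circle_contour(64.5, 64.5, 21, 100)  # 3 px outside the true edge
  out <- evolve_snake(ct, g, snake_params())
  r <- sqrt((out[, 1] - 64.5)^2 + (out[, 2] - 64.5)^2)
  expect_lt(mean(abs(r - 18)), 1)
})

test_that("contours rasterize by the even-odd pixel-center rule", {
  sq <- structure(cbind(x = c(0.5, 9.5, 9.5, 0.5), y = c(0.5, 0.5, 9.5, 9.5)),
                  class = "snake_contour")
  m <- contour_to_mask(sq, c(10, 10))
  expect_equal(sum(m), 81)
  expect_true(all(which(m, arr.ind = TRUE) >= 1) && all(which(m, arr.ind = TRUE) <= 9))

  disk <- disk_mask(20)
  rt <- contour_to_mask(mask_to_contour(disk), dim(disk))
  expect_gt(overlap(rt, disk)$aor2, 0.95)

  tiny <- structure(cbind(x = c(5.1, 5.3, 5.2), y = c(5.1, 5.1, 5.25)),
                    class = "snake_contour")
  expect_warning(m2 <- contour_to_mask(tiny, c(10, 10)), "no pixel center")
  expect_false(any(m2))

  eight <- structure(cbind(x = c(1, 5, 1, 5), y = c(1, 5, 5, 1)),
                     class = "snake_contour")
  expect_error(contour_to_mask(eight, c(6, 6)), "self-intersecting")
})

test_that("refinement is deterministic and improves a shrunken initialization", {
  ph <- make_phantom(phantom_spec(base_radius = 18, noise_sigma = 10, seed = 6))
  # erode the truth to mimic an undersized initialization
  small <- disk_mask(14, size = 128)
  shifted <- matrix(FALSE, 128, 128)
  shifted[(65 - 32):(64 + 32), (65 - 32):(64 + 32)] <-
    small[(65 - 32):(64 + 32), (65 - 32):(64 + 32)]
  r1 <- refine(ph$image, shifted)
  r2 <- refine(ph$image, shifted)
  expect_identical(unclass(r1)[, ], unclass(r2)[, ])
  expect_gt(overlap(r1, ph$mask)$aor2, overlap(shifted, ph$mask)$aor2)
})

test_that("loop removal excises small self-intersections", {
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  pts <- cbind(10 + 5 * cos(th), 10 + 5 * sin(th))
  pts[5, ] <- pts[7, ]         # force a tiny loop
  pts[6, ] <- pts[4, ]
  cleaned <- lesionsnake:::remove_loops(pts)
  expect_false(lesionsnake:::contour_self_intersects(cleaned))
})
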
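test_that("metal segmentation thresholds at 3000 HU", {
  img <- ct_image(matrix(c(2900, 3100, -1000, 3000), 2, 2))
  m <- segment_metal(img)
  expect_identical(as.vector(m$mask), c(FALSE, TRUE, FALSE, TRUE))
  air <- ct_image(matrix(-1000, 4, 4))
  expect_false(any(segment_metal(air)$mask))
  # small-component removal keeps only the large blob
  big <- matrix(-1000, 20, 20)
  big[5:12, 5:12] <- 5000
  big[17, 17] <- 5000
  m2 <- segment_metal(ct_image(big), min_area = 4)
  expect_equal(sum(m2$mask), 64)
  expect_false(m2$mask[17, 17])
})

test_that("relative deviation follows the defined formula", {
  g <- function(kv, mv) {
    relative_deviation(ct_image(matrix(kv, 1, 1)), ct_image(matrix(mv, 1, 1)))[1, 1]
  }
  expect_equal(g(300, 100), 0.5)
  expect_equal(g(123, 123), 0)
  # zero-sum pixels use denominator 1
  expect_equal(g(50, -50), 100)
  expect_equal(g(0, 0), 0)
  a <- ct_image(matrix(0, 2, 2)); b <- ct_image(matrix(0, 3, 3))
  expect_error(relative_deviation(a, b), "not aligned")
})

test_that("deviation weight is a clamped linear ramp", {
  r <- matrix(c(0, 0.05, 0.225, 0.40, 1.4, 10), 2, 3)
  w <- deviation_weight(r, 0.05, 0.40)
  expect_equal(as.vector(w), c(0, 0, 0.5, 1, 1, 1))
  expect_true(all(w >= 0 & w <= 1))
  # monotone in R
  rs <- seq(0, 1, by = 0.01)
  expect_true(all(diff(deviation_weight(matrix(rs, 1), 0.05, 0.4)[1, ]) >= 0))
  expect_error(deviation_weight(r, 0.4, 0.4), "r_lo < r_hi")
})

test_that("distance weight peaks on metal and decays away from it", {
  img <- ct_image(matrix(-1000, 41, 41), c(1, 1))
  img$values[21, 21] <- 5000
  m <- segment_metal(img)
  wd <- distance_weight(m, sigma_mm = 3)
  expect_equal(wd[21, 21], 1)
  expect_true(all(wd >= 0 & wd <= 1))
  # radially decreasing from the single metal pixel
  expect_gt(wd[21, 24], wd[21, 29])
  expect_gt(wd[24, 21], wd[29, 21])
  # empty mask: all-zero map with a warning
  empty <- segment_metal(ct_image(matrix(0, 5, 5)))
  expect_warning(wd0 <- distance_weight(empty), "empty")
  expect_true(all(wd0 == 0))
})

test_that("distance weight decays with distance from the phantom metal", {
  img <- rasterize(default_phantom(), c(128, 128), c(2.36, 2.36))
  m <- segment_metal(img)
  wd <- distance_weight(m, sigma_mm = 30)
  expect_true(all(wd[m$mask] == 1))
  co <- dualmar:::grid_coords(img)
  xg <- matrix(co$x, 128, 128, byrow = TRUE)
  yg <- matrix(co$y, 128, 128)
  # approximate distance to the ellipse via scaled membership
  near <- dualmar:::inside_shape(default_phantom()$shapes[[1]], xg / 10,
                                 yg / 10, margin = 0.5) & !m$mask
  far <- dualmar:::inside_shape(default_phantom()$shapes[[1]], xg / 10,
                                yg / 10, margin = 2.0) &
    !dualmar:::inside_shape(default_phantom()$shapes[[1]], xg / 10, yg / 10,
                            margin = 1.5)
  expect_gt(mean(wd[near]), mean(wd[far]))
})

test_that("fusion limits and convexity hold", {
  set.seed(23)
  kv <- ct_image(matrix(rnorm(400, 100, 300), 20, 20))
  mv <- ct_image(matrix(rnorm(400, 100, 300), 20, 20))
  zero <- matrix(0, 20, 20); one <- matrix(1, 20, 20)
  # w_d == 0 -> fused equals kV
  expect_lt(max(abs(fuse(kv, mv, one, zero)$values - kv$values)), 1e-10)
  # w == w_d == 1 -> fused equals MV
  expect_equal(fuse(kv, mv, one, one)$values, mv$values)
  # identical inputs are a fixed point for any weights
  w <- matrix(runif(400), 20, 20); wd <- matrix(runif(400), 20, 20)
  expect_equal(fuse(kv, kv, w, wd)$values, kv$values)
  # pixel-wise convex combination
  fused <- fuse(kv, mv, w, wd)$values
  expect_true(all(fused >= pmin(kv$values, mv$values) - 1e-9))
  expect_true(all(fused <= pmax(kv$values, mv$values) + 1e-9))
  # monotone MV share: raising w at one pixel moves fused toward MV
  w2 <- w; w2[5, 5] <- min(1, w[5, 5] + 0.3)
  f2 <- fuse(kv, mv, w2, wd)$values
  towards_mv <- abs(f2[5, 5] - mv$values[5, 5]) <=
    abs(fused[5, 5] - mv$values[5, 5])
  expect_true(towards_mv)
})

test_that("the prior replaces metal with tissue fill only", {
  fusedv <- matrix(c(100, 4000, 200, 8000), 2, 2)
  fused <- ct_image(fusedv)
  m <- segment_metal(fused)
  prior <- make_prior(fused, m, fill_hu = 0)
  expect_equal(as.vector(prior$values), c(100, 0, 200, 0))
  expect_lt(max(prior$values), 3000)
  # mismatched mask is rejected; empty mask leaves the image untouched
  wrong <- segment_metal(ct_image(matrix(0, 3, 3)))
  expect_error(make_prior(fused, wrong), "not aligned")
  empty2 <- segment_metal(ct_image(matrix(0, 2, 2) - 1000))
  prior2 <- make_prior(ct_image(matrix(c(1, 2, 3, 4), 2, 2)), empty2)
  expect_equal(as.vector(prior2$values), c(1, 2, 3, 4))
  # all-metal mask gives a constant image
  allm <- segment_metal(ct_image(matrix(5000, 2, 2)))
  expect_true(all(make_prior(ct_image(matrix(5000, 2, 2)), allm, 7)$values == 7))
})
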
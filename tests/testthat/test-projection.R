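test_that("forward projection is linear and mass-preserving", {
  set.seed(42)
  img1 <- ct_image(matrix(runif(64^2, 0, 500), 64, 64), c(2, 2))
  img2 <- ct_image(matrix(runif(64^2, 0, 500), 64, 64), c(2, 2))
  geom <- proj_geometry(img1, views = 40)
  s1 <- forward_project(img1, geom, scale = "raw")
  s2 <- forward_project(img2, geom, scale = "raw")
  both <- ct_image(img1$values + img2$values, c(2, 2))
  s12 <- forward_project(both, geom, scale = "raw")
  expect_equal(s12$values, s1$values + s2$values, tolerance = 1e-10)
  # zero image projects to zero
  zero <- ct_image(matrix(0, 64, 64), c(2, 2))
  expect_true(all(forward_project(zero, geom, scale = "raw")$values == 0))
  # mass conservation: per-view sums agree across views
  disk <- rasterize(phantom_spec(circle_shape(c(0, 0), 5, "water")),
                    c(64, 64), c(2, 2))
  mu <- forward_project(disk, proj_geometry(disk, views = 60))
  sums <- rowSums(mu$values)
  expect_lt(diff(range(sums)) / mean(sums), 0.01)
})

test_that("a centred disk projects identically in every view", {
  # anti-aliased disk (4x4 subpixel coverage) so the oracle isolates the
  # projector's rotational consistency from rasterisation pixelation
  n <- 128
  sub <- seq(-0.375, 0.375, by = 0.25)
  cov <- matrix(0, n, n)
  cc <- (n - 1) / 2
  for (dy in sub) for (dx in sub) {
    y <- ((0:(n - 1)) - cc + dy)
    x <- ((0:(n - 1)) - cc + dx)
    cov <- cov + outer(y, x, function(y, x) (y^2 + x^2 <= 50^2) * 1)
  }
  disk <- ct_image(cov / length(sub)^2 * 1000 - 1000, c(1, 1))
  s <- forward_project(disk, proj_geometry(disk, views = 45))
  ref <- s$values[1, ]
  dev <- apply(s$values, 1, function(row) max(abs(row - ref)))
  expect_lt(max(dev) / max(ref), 0.01)
})

test_that("FBP inverts forward projection and is linear", {
  spec <- phantom_spec(
    circle_shape(c(0, 0), 10, "water"),
    list(ellipse_shape(c(3, 2), c(3, 2), 20, "bone"),
         circle_shape(c(-4, -3), 2, "adipose")))
  img <- rasterize(spec, c(128, 128), c(2, 2))
  geom <- proj_geometry(img, views = 240)
  s <- forward_project(img, geom)
  rec <- fbp(s, "ramp", grid_shape = c(128, 128), pixel_spacing = c(2, 2))
  co <- expand.grid(y = (seq_len(128) - 64.5) * 2, x = (seq_len(128) - 64.5) * 2)
  interior <- matrix(sqrt(co$y^2 + co$x^2) < 85, 128, 128)
  mu_true <- 0.2 * (1 + img$values / 1000)
  mu_rec <- 0.2 * (1 + rec$values / 1000)
  rel_rmse <- sqrt(mean((mu_rec[interior] - mu_true[interior])^2)) /
    mean(mu_true[interior])
  expect_lt(rel_rmse, 0.05)
  # zero sinogram reconstructs to (numerical) air-free zero attenuation
  zero <- sinogram(matrix(0, 60, 91), seq(0, 179, 3), 2)
  rec0 <- fbp(zero, grid_shape = c(64, 64), pixel_spacing = c(2, 2),
              output = "mu")
  expect_true(all(abs(rec0$values) < 1e-12))
  # linearity of the reconstruction operator
  s2 <- sinogram(s$values * 2, s$angles_deg, s$detector_spacing, s$mu_ref)
  rec2 <- fbp(s2, "ramp", grid_shape = c(128, 128), pixel_spacing = c(2, 2),
              output = "mu")
  rec1 <- fbp(s, "ramp", grid_shape = c(128, 128), pixel_spacing = c(2, 2),
              output = "mu")
  expect_equal(rec2$values, 2 * rec1$values, tolerance = 1e-9)
})

test_that("metal trace flags exactly the metal shadow", {
  # empty mask -> empty trace
  empty <- structure(list(mask = matrix(FALSE, 32, 32),
                          threshold_hu = 3000, pixel_spacing = c(2, 2)),
                     class = "metal_mask")
  geom <- proj_geometry(ct_image(matrix(0, 32, 32), c(2, 2)), views = 24)
  tr <- metal_trace(empty, geom)
  expect_false(any(tr$mask))
  expect_equal(nrow(tr$segments), 0)
  # single metal pixel: exactly one short segment per view
  single <- empty
  single$mask[16, 16] <- TRUE
  tr1 <- metal_trace(single, geom, epsilon = 0.05)
  runs <- table(tr1$segments$view)
  expect_equal(length(runs), 24)
  expect_true(all(runs == 1))
  expect_true(all(tr1$segments$last - tr1$segments$first <= 3))
  # convex metal: one segment per view
  spec <- phantom_spec(circle_shape(c(0, 0), 14, "water"),
                       list(ellipse_shape(c(0, 0), c(2.5, 1.8), 0, "steel")))
  img <- rasterize(spec, c(128, 128), c(2.36, 2.36))
  metal <- segment_metal(img)
  geomc <- proj_geometry(img, views = 48)
  trc <- metal_trace(metal, geomc)
  expect_true(all(table(trc$segments$view) == 1))
  # segment bookkeeping reconstructs the mask exactly
  rebuilt <- matrix(FALSE, nrow(trc$mask), ncol(trc$mask))
  for (i in seq_len(nrow(trc$segments))) {
    rebuilt[trc$segments$view[i],
            trc$segments$first[i]:trc$segments$last[i]] <- TRUE
  }
  expect_identical(rebuilt, trc$mask)
  # boundary bins of every segment lie outside the mask
  ok <- vapply(seq_len(nrow(trc$segments)), function(i) {
    v <- trc$segments$view[i]
    l <- trc$segments$first[i] - 1L
    r <- trc$segments$last[i] + 1L
    (l < 1 || !trc$mask[v, l]) && (r > ncol(trc$mask) || !trc$mask[v, r])
  }, TRUE)
  expect_true(all(ok))
})

test_that("sinogram constructor validates geometry", {
  expect_error(sinogram(matrix(0, 3, 4), c(0, 90), 1), "one angle per")
  expect_error(sinogram(matrix(0, 3, 4), c(0, 90, 45), 1), "increasing")
  expect_error(sinogram(matrix(c(0, Inf), 1, 2), 0, 1), "finite")
  expect_error(sinogram(matrix(0, 2, 2), c(0, 400), 1), "less than 360")
})
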
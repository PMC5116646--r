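test_that("calibration curve interpolates knots exactly and linearly", {
  cur <- fit_calibration(cbind(c(-1000, 0), c(-1000, 0)))
  x <- seq(-1000, 0, by = 50)
  expect_equal(dualmar:::eval_calibration(cur, x), x)  # identity segment
  cur2 <- fit_calibration(cbind(c(0, 100), c(0, 200)))
  expect_equal(dualmar:::eval_calibration(cur2, 50), 100)
  # exact at every knot; second differences vanish between knots
  set.seed(3)
  knots <- cbind(sort(runif(6, -900, 2000)), rnorm(6, 0, 500))
  cur3 <- fit_calibration(knots)
  expect_equal(dualmar:::eval_calibration(cur3, knots[, 1]), knots[, 2])
  xs <- seq(knots[2, 1] + 1e-6, knots[3, 1] - 1e-6, length.out = 30)
  ys <- dualmar:::eval_calibration(cur3, xs)
  expect_lt(max(abs(diff(diff(ys)))), 1e-8)
  expect_error(fit_calibration(cbind(c(0, 0), c(1, 2))), "duplicate")
  expect_error(fit_calibration(cbind(1, 1)), "at least 2")
})

test_that("calibration extrapolates linearly beyond the outer knots", {
  cur <- fit_calibration(cbind(c(0, 100, 300), c(0, 200, 500)))
  # left segment slope 2, right segment slope 1.5
  expect_equal(dualmar:::eval_calibration(cur, -50), -100)
  expect_equal(dualmar:::eval_calibration(cur, 5000), 500 + 1.5 * 4700)
})

test_that("apply_calibration maps pixels and preserves geometry and order", {
  img <- ct_image(matrix(c(-500, 0, 250, 800), 2, 2), c(1.3, 1.3))
  ident <- fit_calibration(cbind(c(-1000, 1000), c(-1000, 1000)))
  expect_equal(apply_calibration(img, ident)$values, img$values)
  cur <- fit_calibration(cbind(c(-1000, 0, 1000), c(-1000, 100, 1500)))
  out <- apply_calibration(img, cur)
  expect_equal(out$pixel_spacing, img$pixel_spacing)
  expect_equal(order(out$values), order(img$values))  # monotone map
  const <- ct_image(matrix(0, 3, 3))
  expect_true(all(apply_calibration(const, cur)$values == 100))
})

test_that("fitted rod pairs reproduce simulated rod means at the knots", {
  cur <- study_calibration(seed = 1, n_rods = 4)
  expect_equal(nrow(cur$knots), 4)
  expect_true(all(diff(cur$knots$hu_mv) > 0))
  # by construction the curve passes through every measured pair
  expect_equal(dualmar:::eval_calibration(cur, cur$knots$hu_mv),
               cur$knots$hu_kv)
  # kV rod HU spread exceeds MV spread (higher soft-tissue contrast at kV)
  expect_gt(diff(range(cur$knots$hu_kv)), diff(range(cur$knots$hu_mv)))
})

test_that("bilinear resampling is exact for constants and affine ramps", {
  const <- ct_image(matrix(42, 40, 40), c(2, 2))
  target <- ct_image(matrix(0, 20, 20), c(4, 4))
  out <- resample_to_grid(const, target)
  expect_true(all(abs(out$values - 42) < 1e-12))
  # identity resample
  expect_equal(resample_to_grid(const, const)$values, const$values,
               tolerance = 1e-12)
  # linear ramp to half spacing stays a ramp
  co <- dualmar:::grid_coords(ct_image(matrix(0, 32, 32), c(4, 4)))
  ramp <- ct_image(outer(co$y, co$x, function(y, x) 3 * x + 2 * y),
                   c(4, 4))
  fine <- ct_image(matrix(0, 48, 48), c(2, 2))
  outf <- resample_to_grid(ramp, fine)
  cof <- dualmar:::grid_coords(outf)
  expected <- outer(cof$y, cof$x, function(y, x) 3 * x + 2 * y)
  inside <- abs(matrix(cof$y, 48, 48)) < 55 & abs(matrix(cof$x, 48, 48,
                                                         byrow = TRUE)) < 55
  expect_lt(max(abs(outf$values - expected)[inside]), 1e-9)
})

test_that("rigid transforms compose with their inverse to identity", {
  tr <- rigid_transform(c(4.5, -2.25), 12)
  inv <- invert_rigid(tr)
  co <- dualmar:::grid_coords(ct_image(matrix(0, 64, 64), c(2, 2)))
  ramp <- ct_image(outer(co$y, co$x, function(y, x) 2 * x - y + 30), c(2, 2))
  back <- apply_rigid(apply_rigid(ramp, tr), inv)
  centre <- 22:42
  expect_equal(back$values[centre, centre], ramp$values[centre, centre],
               tolerance = 1e-9)
})

test_that("registration recovers synthetic shifts and rotations", {
  spec <- phantom_spec(circle_shape(c(0, 0), 11, "water"),
                       list(circle_shape(c(5, 2), 1.5, "bone"),
                            ellipse_shape(c(-4, -3), c(2, 1), 30, "adipose"),
                            circle_shape(c(0, 6), 1, "lung")))
  fixed <- rasterize(spec, c(96, 96), c(2.5, 2.5))
  # identity case
  same <- rigid_register(fixed, fixed, max_shift = 6, max_rot = 6,
                         coarse_step = 2, fine_step = 0.25)
  expect_lt(max(abs(same$transform$translation)), 0.25)
  expect_lt(abs(same$transform$rotation), 0.25)
  # pure shift: fixed displaced by +3 px rows (7.5 mm)
  moving <- apply_rigid(fixed, rigid_transform(c(7.5, 0), 0))
  reg <- rigid_register(moving, fixed, max_shift = 10, max_rot = 2,
                        coarse_step = 2.5, fine_step = 0.1)
  expect_lt(abs(reg$transform$translation[1] + 7.5), 0.5 * 2.5)  # 0.5 px
  expect_lt(abs(reg$transform$translation[2]), 0.5 * 2.5)
  # pure rotation by 5 degrees
  moving_rot <- apply_rigid(fixed, rigid_transform(c(0, 0), 5))
  reg_rot <- rigid_register(moving_rot, fixed, max_shift = 2, max_rot = 10,
                            coarse_step = 2.5, fine_step = 0.1)
  expect_lt(abs(reg_rot$transform$rotation + 5), 0.5)
})

test_that("transform and calibration serialisation round trips", {
  tmp <- withr::local_tempdir()
  tr <- rigid_transform(c(1.25, -0.5), 3.75)
  write_rigid(tr, file.path(tmp, "t.json"))
  tr2 <- read_rigid(file.path(tmp, "t.json"))
  expect_equal(tr2$translation, tr$translation)
  expect_equal(tr2$rotation, tr$rotation)
  cur <- fit_calibration(cbind(c(-500, 0, 700), c(-480, 30, 900)))
  write_calibration(cur, file.path(tmp, "cal.csv"))
  expect_equal(read_calibration(file.path(tmp, "cal.csv"))$knots, cur$knots)
})
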
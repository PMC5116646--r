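test_that("replace_trace matches the worked boundary-offset example", {
  pkv <- make_sino(matrix(c(1, 2, 9, 9, 2, 1), 1, 6))
  pprior <- make_sino(matrix(c(1, 2, 4, 4, 2, 1), 1, 6))
  mask <- matrix(c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE), 1, 6)
  tr <- dualmar:::trace_from_mask(mask)
  out <- replace_trace(pkv, pprior, tr)
  expect_equal(out$values, matrix(c(1, 2, 4, 4, 2, 1), 1, 6))
})

test_that("replace_trace reduces to the prior when boundary offsets vanish", {
  set.seed(7)
  pprior <- matrix(rnorm(5 * 10, 3), 5, 10)
  pkv <- pprior + matrix(rnorm(50, 0, 2), 5, 10)
  mask <- matrix(FALSE, 5, 10)
  mask[, 4:6] <- TRUE
  pkv[, c(3, 7)] <- pprior[, c(3, 7)]  # agree at both boundaries
  out <- replace_trace(make_sino(pkv), make_sino(pprior),
                       dualmar:::trace_from_mask(mask))
  expect_equal(out$values[, 4:6], pprior[, 4:6])
})

test_that("bins outside the trace are bit-identical after replacement", {
  set.seed(11)
  for (i in 1:20) {
    cs <- random_trace_case()
    out <- replace_trace(make_sino(cs$pkv), make_sino(cs$pprior),
                         dualmar:::trace_from_mask(cs$mask))
    expect_identical(out$values[!cs$mask], cs$pkv[!cs$mask])
  }
})

test_that("the blend is continuous with the measured data at segment ends", {
  set.seed(13)
  pkv <- matrix(rnorm(3 * 16, 4), 3, 16)
  pprior <- matrix(rnorm(3 * 16, 4), 3, 16)
  mask <- matrix(FALSE, 3, 16)
  mask[1, 5:9] <- TRUE; mask[2, 2:3] <- TRUE; mask[3, 10:14] <- TRUE
  out <- replace_trace(make_sino(pkv), make_sino(pprior),
                       dualmar:::trace_from_mask(mask))$values
  # evaluating the blend at the boundary bins returns the boundary offsets,
  # so the first/last replaced bins interpolate toward the measured values
  seg <- c(5, 9); v <- 1
  jj <- seg[1] - 1; jr <- seg[2] + 1; delta <- seg[2] - seg[1] + 1
  dl <- pkv[v, jj] - pprior[v, jj]; dr <- pkv[v, jr] - pprior[v, jr]
  off_first <- ((jr - seg[1]) * dl + (seg[1] - jj) * dr) / (delta + 1)
  expect_equal(out[v, seg[1]], pprior[v, seg[1]] + off_first)
  off_at_jj <- ((jr - jj) * dl + 0 * dr) / (delta + 1)
  expect_equal(off_at_jj, dl)  # blend equals the left offset at b = jj
})

test_that("edge-touching segments fall back to one-sided offsets", {
  pkv <- matrix(c(5, 6, 7, 1, 2, 3), 1, 6)
  pprior <- matrix(c(1, 1, 1, 1, 1, 1), 1, 6)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), 1, 6)
  out <- replace_trace(make_sino(pkv), make_sino(pprior),
                       dualmar:::trace_from_mask(mask))
  expect_equal(attr(out, "edge_segments"), 1L)
  expect_equal(out$values[1, 1:2], 1 + c(7 - 1, 7 - 1))
})

test_that("limar interpolation equals replace_trace with a zero prior", {
  set.seed(17)
  for (i in 1:10) {
    cs <- random_trace_case(6, 14)
    tr <- dualmar:::trace_from_mask(cs$mask)
    zero <- matrix(0, 6, 14)
    via_replace <- replace_trace(make_sino(cs$pkv), make_sino(zero), tr)
    via_limar <- dualmar:::interp_trace_linear(cs$pkv, tr)
    expect_equal(via_limar, via_replace$values, tolerance = 1e-12)
  }
})

test_that("nmar with a constant prior sinogram equals limar exactly", {
  spec <- phantom_spec(circle_shape(c(0, 0), 12, "water"),
                       list(ellipse_shape(c(0, 0), c(2, 1.5), 0, "steel"),
                            circle_shape(c(6, 0), 1.5, "bone")))
  img <- rasterize(spec, c(96, 96), c(3, 3))
  cfg <- mar_config(views = 90, filter = "ramp")
  metal <- segment_metal(img)
  li <- limar(img, metal, cfg)
  flat <- li$p_kv
  flat$values[] <- 2.5  # constant normalisation cancels through the blend
  nm <- nmar(img, metal, flat, cfg)
  expect_equal(nm$corrected$values, li$corrected$values, tolerance = 1e-9)
})

test_that("MAR variants reduce to a plain round trip without metal", {
  disk <- rasterize(phantom_spec(circle_shape(c(0, 0), 10, "water"),
                                 list(circle_shape(c(4, 0), 2, "bone"))),
                    c(96, 96), c(3, 3))
  cfg <- mar_config(views = 120, filter = "ramp")
  geom <- proj_geometry(disk, views = 120)
  plain <- fbp(forward_project(disk, geom), "ramp", grid_shape = c(96, 96),
               pixel_spacing = c(3, 3))
  li <- limar(disk, config = cfg)
  expect_equal(li$corrected$values, plain$values, tolerance = 1e-9)
  fu <- mar_correct(disk, disk, cfg)
  expect_equal(fu$corrected$values, plain$values, tolerance = 1e-9)
  nm <- nmar(disk, segment_metal(disk), disk, cfg)
  expect_equal(nm$corrected$values, plain$values, tolerance = 1e-9)
})

test_that("reinsert_metal swaps exactly the masked pixels", {
  rec <- ct_image(matrix(0, 8, 8), c(1, 1))
  src <- ct_image(matrix(7000, 8, 8), c(1, 1))
  mask <- structure(list(mask = matrix(FALSE, 8, 8), threshold_hu = 3000,
                         pixel_spacing = c(1, 1)), class = "metal_mask")
  expect_equal(reinsert_metal(rec, src, mask)$values, rec$values)
  mask$mask[3:4, 5] <- TRUE
  out <- reinsert_metal(rec, src, mask)
  expect_equal(out$values[3:4, 5], c(7000, 7000))
  expect_equal(sum(out$values), 14000)
  all_mask <- mask; all_mask$mask[] <- TRUE
  expect_equal(reinsert_metal(rec, src, all_mask)$values, src$values)
  # fixed-value reinsertion
  out_fixed <- reinsert_metal(rec, 8000, mask)
  expect_equal(out_fixed$values[3, 5], 8000)
})
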
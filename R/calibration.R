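#' Piecewise-linear MV-to-kV HU calibration
#'
#' The attenuation of a material differs between MV and kV beams, so MV HU
#' must be mapped to pseudo-kV HU before fusion. The map is the piecewise
#' linear interpolant through paired rod measurements
#' `(mean HU_MV, mean HU_kV)`; beyond the outermost knots the end segments
#' continue linearly (metal HU lies far above the densest calibration rod,
#' and clamping would destroy its pseudo-kV value).
#'
#' @param pairs 2-column matrix or data frame `(hu_mv, hu_kv)`, >= 2 rows,
#'   `hu_mv` values distinct.
#' @return object of class `calibration_curve` with a `knots` data frame.
#' @export
fit_calibration <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 2) stop("need at least 2 paired rod measurements")
  if (anyDuplicated(pairs[, 1])) {
    stop("degenerate fit: duplicate HU_MV values")
  }
  ord <- order(pairs[, 1])
  knots <- data.frame(hu_mv = pairs[ord, 1], hu_kv = pairs[ord, 2])
  structure(list(knots = knots), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %d knots, HU_MV in [%g, %g]\n",
              nrow(x$knots), min(x$knots$hu_mv), max(x$knots$hu_mv)))
  invisible(x)
}

# Evaluate the curve at arbitrary HU_MV values (vectorised), with linear
# extrapolation from the end segments.
eval_calibration <- function(curve, hu_mv) {
  k <- curve$knots
  n <- nrow(k)
  out <- approx(k$hu_mv, k$hu_kv, xout = hu_mv, rule = 2)$y
  lo <- hu_mv < k$hu_mv[1]
  if (any(lo)) {
    s <- (k$hu_kv[2] - k$hu_kv[1]) / (k$hu_mv[2] - k$hu_mv[1])
    out[lo] <- k$hu_kv[1] + s * (hu_mv[lo] - k$hu_mv[1])
  }
  hi <- hu_mv > k$hu_mv[n]
  if (any(hi)) {
    s <- (k$hu_kv[n] - k$hu_kv[n - 1]) / (k$hu_mv[n] - k$hu_mv[n - 1])
    out[hi] <- k$hu_kv[n] + s * (hu_mv[hi] - k$hu_mv[n])
  }
  out
}

#' Apply a calibration curve to an image
#'
#' Per-pixel evaluation of the piecewise-linear map; grid geometry is
#' unchanged. The result is the pseudo-kV version of an MV image.
#'
#' @param image a `ct_image` in MV HU.
#' @param curve a `calibration_curve`.
#' @return a `ct_image` in pseudo-kV HU.
#' @export
apply_calibration <- function(image, curve) {
  vals <- matrix(eval_calibration(curve, as.vector(image$values)),
                 nrow(image$values), ncol(image$values))
  ct_image(vals, pixel_spacing = image$pixel_spacing, origin = image$origin,
           bit_depth_range = image$bit_depth_range)
}

#' Measure rod HU pairs on a simulated calibration scan
#'
#' Means of each rod's interior (shrunk by `margin_cm` to avoid partial
#' volume) in a co-registered MV / kV image pair of a [calibration_phantom()].
#'
#' @param spec the `calibration_phantom()` spec that was scanned.
#' @param image_mv,image_kv reconstructed `ct_image`s of the phantom.
#' @param margin_cm shrink applied to each rod before averaging.
#' @return data frame `(hu_mv, hu_kv)`, one row per rod.
#' @export
measure_rod_pairs <- function(spec, image_mv, image_kv, margin_cm = 0.3) {
  check_same_grid(image_mv, image_kv)
  co <- grid_coords(image_mv)
  xg <- matrix(co$x / 10, length(co$y), length(co$x), byrow = TRUE)
  yg <- matrix(co$y / 10, length(co$y), length(co$x))
  rows <- lapply(spec$shapes, function(sh) {
    m <- inside_shape(sh, xg, yg, margin = -margin_cm)
    if (!any(m)) return(NULL)
    data.frame(hu_mv = mean(image_mv$values[m]),
               hu_kv = mean(image_kv$values[m]))
  })
  do.call(rbind, rows)
}

#' Read / write a calibration curve as two-column CSV
#'
#' @param curve a `calibration_curve`.
#' @param path CSV file with header `hu_mv,hu_kv`.
#' @export
write_calibration <- function(curve, path) {
  utils::write.csv(curve$knots, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  fit_calibration(utils::read.csv(path))
}
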
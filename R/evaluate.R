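#' Percentage-difference map
#'
#' `d_i = 100 * (t_i - tref_i) / tref_i`, with the denominator replaced by
#' 1 wherever the reference is zero, so the map is finite everywhere. The
#' signed convention keeps bright (positive) and dark (negative) artifacts
#' distinguishable.
#'
#' @param test,reference `ct_image`s on the same grid.
#' @return numeric matrix of percentages.
#' @export
percent_diff_map <- function(test, reference) {
  check_same_grid(test, reference)
  den <- reference$values
  den[den == 0] <- 1
  100 * (test$values - reference$values) / den
}

#' Line profile through a point
#'
#' HU values along the full image row (`horizontal`) or column
#' (`vertical`) passing through a physical point, with positions attached.
#'
#' @param image a `ct_image`.
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param through length-2 physical (x, y) position in mm; default the
#'   grid centre.
#' @return data frame with `position_mm` (along the profile) and `hu`.
#' @export
line_profile <- function(image, orientation = c("horizontal", "vertical"),
                         through = NULL) {
  orientation <- match.arg(orientation)
  co <- grid_coords(image)
  d <- dim(image$values)
  if (is.null(through)) {
    through <- c(mean(range(co$x)), mean(range(co$y)))
  }
  r <- round((through[2] - image$origin[1]) / image$pixel_spacing[1]) + 1
  c <- round((through[1] - image$origin[2]) / image$pixel_spacing[2]) + 1
  if (r < 1 || r > d[1] || c < 1 || c > d[2]) {
    stop("profile point lies outside the grid")
  }
  if (orientation == "horizontal") {
    data.frame(position_mm = co$x, hu = image$values[r, ])
  } else {
    data.frame(position_mm = co$y, hu = image$values[, c])
  }
}

#' Region-based error metrics
#'
#' Per-region statistics of `test - reference`: mean absolute error, mean
#' signed error and maximum absolute error, in HU.
#'
#' @param test,reference `ct_image`s on the same grid.
#' @param regions named list of logical masks (e.g. from
#'   [standard_regions()]); empty regions are skipped with a warning.
#' @return data frame with columns `region`, `n_pixels`, `mae_hu`,
#'   `mean_err_hu`, `max_abs_err_hu`.
#' @export
region_metrics <- function(test, reference, regions) {
  check_same_grid(test, reference)
  err <- test$values - reference$values
  rows <- lapply(names(regions), function(nm) {
    m <- regions[[nm]]
    if (!any(m)) {
      warning("region '", nm, "' is empty; skipped")
      return(NULL)
    }
    e <- err[m]
    data.frame(region = nm, n_pixels = sum(m), mae_hu = mean(abs(e)),
               mean_err_hu = mean(e), max_abs_err_hu = max(abs(e)))
  })
  do.call(rbind, rows)
}

#' Standard artifact regions of a metal phantom
#'
#' Geometric masks derived from the phantom spec, operationalising the
#' qualitative artifact zones: 1 cm-wide bands along the metal ellipse's
#' long and short axes (outside an expanded metal margin, inside the
#' body), the central hole disk, the metal itself (minus hole), and a
#' far-field annulus.
#'
#' @param spec a `phantom_spec` whose first high-density (density >= 5)
#'   shape is the metal; air shapes inside it are holes.
#' @param image `ct_image` defining the grid.
#' @param band_halfwidth_mm half-width of the axis bands.
#' @param margin_mm exclusion margin around the metal for the bands.
#' @param band_extent_mm how far each band reaches beyond the metal edge
#'   along its axis; streak and band artifacts concentrate within a few cm
#'   of the metal, so the bands cover that neighbourhood rather than the
#'   whole body.
#' @return named list of logical masks: `metal`, `hole`, `long_axis_band`,
#'   `short_axis_band`, `far_field`.
#' @export
standard_regions <- function(spec, image, band_halfwidth_mm = 5,
                             margin_mm = 2, band_extent_mm = 30) {
  dens <- vapply(spec$shapes, function(s) spec$materials[[s$material]]$density, 0)
  mi <- which(dens >= 5)
  if (!length(mi)) stop("phantom has no high-density (metal) shape")
  metal_sh <- spec$shapes[[mi[1]]]
  holes <- Filter(function(s) {
    spec$materials[[s$material]]$density == 0 &&
      all(inside_shape(metal_sh, shape_boundary(s)[, "x"],
                       shape_boundary(s)[, "y"], margin = 1e-6))
  }, spec$shapes)
  co <- grid_coords(image)
  xg <- matrix(co$x / 10, length(co$y), length(co$x), byrow = TRUE)
  yg <- matrix(co$y / 10, length(co$y), length(co$x))
  in_metal <- inside_shape(metal_sh, xg, yg)
  hole_mask <- matrix(FALSE, nrow(xg), ncol(xg))
  for (h in holes) {
    hole_mask <- hole_mask | inside_shape(h, xg, yg, margin = -0.1)
    in_metal <- in_metal & !inside_shape(h, xg, yg)
  }
  near_metal <- inside_shape(metal_sh, xg, yg, margin = margin_mm / 10)
  in_body <- inside_shape(spec$body, xg, yg, margin = -0.5)
  th <- metal_sh$rotation * pi / 180
  cx <- metal_sh$center[1]; cy <- metal_sh$center[2]
  u <- (xg - cx) * cos(th) - (yg - cy) * sin(th)   # along long axis
  v <- (xg - cx) * sin(th) + (yg - cy) * cos(th)   # along short axis
  bw <- band_halfwidth_mm / 10
  ext <- band_extent_mm / 10
  semi <- if (metal_sh$type == "ellipse") metal_sh$semi_axes else
    metal_sh$half_size
  long_band <- abs(v) <= bw & abs(u) <= semi[1] + ext & in_body & !near_metal
  short_band <- abs(u) <= bw & abs(v) <= semi[2] + ext & in_body & !near_metal
  rr <- sqrt((xg - cx)^2 + (yg - cy)^2)
  far <- rr >= 8 & rr <= 11 & in_body & !long_band & !short_band
  list(metal = in_metal, hole = hole_mask, long_axis_band = long_band,
       short_axis_band = short_band, far_field = far)
}

#' Write evaluation outputs as CSV
#'
#' @param metrics data frame from [region_metrics()].
#' @param profile data frame from [line_profile()].
#' @param path output file.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}
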
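#' Rigid transform
#'
#' Translation (mm) plus rotation (degrees, counter-clockwise) about the
#' grid centre, applied to an image by resampling.
#'
#' @param translation length-2 (row, col) shift in mm.
#' @param rotation degrees.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0), rotation = 0) {
  structure(list(translation = as.numeric(rep_len(translation, 2L)),
                 rotation = as.numeric(rotation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> dy %.3g mm, dx %.3g mm, %.3g deg\n",
              x$translation[1], x$translation[2], x$rotation))
  invisible(x)
}

#' Apply a rigid transform to an image
#'
#' The output pixel at physical position `p` (relative to the grid centre)
#' samples the input at `R(-theta) (p - t)`, i.e. the image content is
#' shifted by `t` and rotated by `theta`.
#'
#' @param image a `ct_image`.
#' @param transform a `rigid_transform`.
#' @param fill HU fill for out-of-field pixels.
#' @return transformed `ct_image` on the same grid.
#' @export
apply_rigid <- function(image, transform, fill = -1000) {
  d <- dim(image$values)
  cy <- (d[1] - 1) / 2; cx <- (d[2] - 1) / 2
  r_idx <- matrix(seq_len(d[1]) - 1, d[1], d[2])
  c_idx <- matrix(seq_len(d[2]) - 1, d[1], d[2], byrow = TRUE)
  y <- (r_idx - cy) * image$pixel_spacing[1] - transform$translation[1]
  x <- (c_idx - cx) * image$pixel_spacing[2] - transform$translation[2]
  th <- -transform$rotation * pi / 180
  xs <- x * cos(th) - y * sin(th)
  ys <- x * sin(th) + y * cos(th)
  r <- ys / image$pixel_spacing[1] + cy + 1
  c <- xs / image$pixel_spacing[2] + cx + 1
  vals <- matrix(bilinear_sample(image$values, as.vector(r), as.vector(c),
                                 fill = fill), d[1], d[2])
  ct_image(vals, pixel_spacing = image$pixel_spacing, origin = image$origin,
           bit_depth_range = image$bit_depth_range)
}

#' Invert a rigid transform
#'
#' @param transform a `rigid_transform`.
#' @return the inverse `rigid_transform` (composition yields identity
#'   within float tolerance).
#' @export
invert_rigid <- function(transform) {
  th <- -transform$rotation * pi / 180
  t <- transform$translation
  # inverse: rotate back, then shift by -R(-theta) t
  rigid_transform(c(-(t[2] * sin(th) + t[1] * cos(th)),
                    -(t[2] * cos(th) - t[1] * sin(th))),
                  -transform$rotation)
}

#' Rigid registration by coarse-to-fine exhaustive search
#'
#' Finds the `(ty, tx, theta)` minimising the mean squared HU difference
#' between the transformed moving image and the fixed image, by an
#' exhaustive coarse grid followed by local refinement down to
#' `fine_step`. Deterministic and derivative-free; adequate for rigid
#' phantom alignment. When `metal_threshold` is given, pixels at or above
#' it in either image are excluded from the metric (artifacts differ
#' between modalities and would bias the MSE).
#'
#' @param moving,fixed `ct_image`s on the same grid.
#' @param max_shift search bound for |translation|, mm.
#' @param max_rot search bound for |rotation|, degrees.
#' @param coarse_step initial grid step (mm and degrees).
#' @param fine_step refinement target (mm and degrees).
#' @param metal_threshold optional HU threshold masking metal out of the
#'   metric.
#' @return list with `transform` (`rigid_transform`), `registered`
#'   (transformed moving image) and `mse`.
#' @export
rigid_register <- function(moving, fixed, max_shift = 10, max_rot = 10,
                           coarse_step = 2, fine_step = 0.1,
                           metal_threshold = NULL) {
  check_same_grid(moving, fixed)
  weight <- NULL
  if (!is.null(metal_threshold)) {
    weight <- fixed$values < metal_threshold
  }
  score <- function(ty, tx, th) {
    tr <- apply_rigid(moving, rigid_transform(c(ty, tx), th))
    d <- tr$values - fixed$values
    keep <- tr$values > -1000 + 1e-6  # ignore fill
    if (!is.null(weight)) keep <- keep & weight & (tr$values < metal_threshold)
    if (!any(keep)) return(Inf)
    mean(d[keep]^2)
  }
  grid_vals <- function(center, half, step, bound) {
    v <- center + seq(-half, half, by = step)
    v[abs(v) <= bound + 1e-9]
  }
  best <- c(0, 0, 0); best_mse <- Inf
  ty_s <- tx_s <- seq(-max_shift, max_shift, by = coarse_step)
  th_s <- seq(-max_rot, max_rot, by = coarse_step)
  for (th in th_s) for (ty in ty_s) for (tx in tx_s) {
    m <- score(ty, tx, th)
    if (m < best_mse) { best_mse <- m; best <- c(ty, tx, th) }
  }
  step <- coarse_step / 2
  while (step >= fine_step) {
    cand <- expand.grid(ty = grid_vals(best[1], step, step, max_shift),
                        tx = grid_vals(best[2], step, step, max_shift),
                        th = grid_vals(best[3], step, step, max_rot))
    for (i in seq_len(nrow(cand))) {
      m <- score(cand$ty[i], cand$tx[i], cand$th[i])
      if (m < best_mse) {
        best_mse <- m
        best <- as.numeric(cand[i, ])
      }
    }
    step <- step / 2
  }
  if (!is.finite(best_mse)) stop("registration failed: no overlap")
  tr <- rigid_transform(best[1:2], best[3])
  list(transform = tr, registered = apply_rigid(moving, tr), mse = best_mse)
}

#' Serialise a rigid transform to / from JSON
#'
#' @param transform a `rigid_transform`.
#' @param path JSON file path.
#' @export
write_rigid <- function(transform, path) {
  jsonlite::write_json(list(translation = transform$translation,
                            rotation = transform$rotation),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_rigid
#' @export
read_rigid <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$translation, x$rotation)
}
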
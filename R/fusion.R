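#' Segment metal by HU thresholding
#'
#' Metal pixels are those at or above `threshold_hu` (default 3000 HU, the
#' threshold used on the MV image, which shows metal without artifacts).
#' Optionally removes connected components smaller than `min_area` pixels
#' (4-connectivity; default 0 = keep all).
#'
#' @param image a `ct_image`.
#' @param threshold_hu HU threshold.
#' @param min_area minimum component area in pixels.
#' @return object of class `metal_mask`: logical `mask`, `threshold_hu`,
#'   and the grid's `pixel_spacing`.
#' @export
segment_metal <- function(image, threshold_hu = 3000, min_area = 0) {
  mask <- image$values >= threshold_hu
  if (min_area > 0 && any(mask)) {
    mask <- drop_small_components(mask, min_area)
  }
  structure(list(mask = mask, threshold_hu = threshold_hu,
                 pixel_spacing = image$pixel_spacing),
            class = "metal_mask")
}

#' @export
print.metal_mask <- function(x, ...) {
  cat(sprintf("<metal_mask> %d px >= %g HU\n", sum(x$mask), x$threshold_hu))
  invisible(x)
}

# Remove 4-connected components below min_area (simple queue flood fill).
drop_small_components <- function(mask, min_area) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  keep <- mask
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    comp <- integer(0)
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, p)
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          q <- (cc - 1L) * nr + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- nxt
            queue <- c(queue, q)
          }
        }
      }
    }
    if (length(comp) < min_area) keep[comp] <- FALSE
  }
  keep
}

#' Relative deviation between kV and MV images
#'
#' `R(i,j) = |I_kv - I_mv| / |I_kv + I_mv|`, with the denominator replaced
#' by 1 wherever `I_kv + I_mv = 0`. Large R marks pixels where the two
#' modalities disagree — typically artifact-corrupted kV pixels near metal.
#'
#' @param i_kv,i_mv `ct_image`s on the same grid (MV already calibrated to
#'   pseudo-kV HU).
#' @return numeric matrix R >= 0.
#' @export
relative_deviation <- function(i_kv, i_mv) {
  check_same_grid(i_kv, i_mv)
  den <- abs(i_kv$values + i_mv$values)
  den[den == 0] <- 1
  abs(i_kv$values - i_mv$values) / den
}

#' Deviation weight curve
#'
#' Monotone saturating map from relative deviation R to the MV weight w:
#' 0 below `r_lo`, 1 above `r_hi`, linear in between. Pixels where the
#' modalities agree keep the sharper, quieter kV value; pixels where they
#' disagree (artifacts) lean on MV.
#'
#' @param r matrix of relative deviations (from [relative_deviation()]).
#' @param r_lo,r_hi ramp ends, `0 <= r_lo < r_hi`.
#' @return matrix w in `[0, 1]`.
#' @export
deviation_weight <- function(r, r_lo = 0.05, r_hi = 0.40) {
  if (r_lo < 0 || r_lo >= r_hi) stop("need 0 <= r_lo < r_hi")
  pmin(pmax((r - r_lo) / (r_hi - r_lo), 0), 1)
}

#' Distance-to-metal weight
#'
#' Gaussian low-pass filter of the binary metal mask (sigma in mm,
#' converted to pixels through the grid spacing), rescaled so the maximum
#' over metal pixels is 1. The weight is 1 on the metal, decays with
#' distance from it, and vanishes far away, confining the MV contribution
#' to the artifact neighbourhood.
#'
#' @param metal a `metal_mask`.
#' @param sigma_mm Gaussian sigma in mm, > 0.
#' @return matrix w_d in `[0, 1]`; for an empty mask an all-zero map with
#'   attribute `empty_mask = TRUE`.
#' @export
distance_weight <- function(metal, sigma_mm = 30) {
  if (sigma_mm <= 0) stop("sigma_mm must be > 0")
  if (!any(metal$mask)) {
    warning("empty metal mask: distance weight is identically zero")
    out <- matrix(0, nrow(metal$mask), ncol(metal$mask))
    attr(out, "empty_mask") <- TRUE
    return(out)
  }
  sig_px <- sigma_mm / metal$pixel_spacing
  wd <- gaussian_blur_px(metal$mask * 1, sig_px)
  wd <- wd / max(wd[metal$mask])
  wd[metal$mask] <- 1
  pmin(pmax(wd, 0), 1)
}

#' Fuse kV and MV images into a prior candidate
#'
#' `I_fused = w_d * (w * I_mv + (1 - w) * I_kv) + (1 - w_d) * I_kv`: the
#' per-pixel MV share is `w_d * w`, so the fused image follows MV where the
#' modalities disagree near metal and reverts to kV elsewhere.
#'
#' @param i_kv kV `ct_image`.
#' @param i_mv_pseudo calibrated, registered MV `ct_image`.
#' @param w,w_d weight matrices in `[0, 1]` (see [deviation_weight()],
#'   [distance_weight()]).
#' @return fused `ct_image`.
#' @export
fuse <- function(i_kv, i_mv_pseudo, w, w_d) {
  check_same_grid(i_kv, i_mv_pseudo)
  if (!identical(dim(w), dim(i_kv$values)) ||
      !identical(dim(w_d), dim(i_kv$values))) {
    stop("weight maps are not aligned with the images")
  }
  share <- w_d * w
  vals <- share * i_mv_pseudo$values + (1 - share) * i_kv$values
  ct_image(vals, pixel_spacing = i_kv$pixel_spacing, origin = i_kv$origin,
           bit_depth_range = i_kv$bit_depth_range)
}

#' Build the prior image
#'
#' Copies the fused image and replaces metal pixels with `fill_hu`
#' (default 0 HU = water), so the forward-projected prior carries tissue
#' structure but no metal.
#'
#' @param fused fused `ct_image`.
#' @param metal a `metal_mask` on the same grid.
#' @param fill_hu HU written into the metal region.
#' @return prior `ct_image`.
#' @export
make_prior <- function(fused, metal, fill_hu = 0) {
  if (!identical(dim(metal$mask), dim(fused$values))) {
    stop("metal mask is not aligned with the fused image")
  }
  vals <- fused$values
  vals[metal$mask] <- fill_hu
  ct_image(vals, pixel_spacing = fused$pixel_spacing, origin = fused$origin,
           bit_depth_range = fused$bit_depth_range)
}
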
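#' Sinogram container
#'
#' Parallel-beam projection data: `values[a, b]` is the line integral seen
#' by detector bin `b` under view `a` (flat index `k = (a - 1) * n + b`).
#' Values are dimensionless attenuation line integrals (mu in 1/cm
#' integrated over cm). `mu_ref` records the water attenuation (1/cm) used
#' to map HU to mu, so reconstruction can invert the scaling.
#'
#' @param values m x n numeric matrix (views x bins), finite.
#' @param angles_deg view angles in degrees, strictly increasing, spanning
#'   less than 360.
#' @param detector_spacing bin pitch in mm.
#' @param mu_ref reference water attenuation in 1/cm.
#' @return an object of class `sinogram`.
#' @export
sinogram <- function(values, angles_deg, detector_spacing, mu_ref = 0.2) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("sinogram values must be finite")
  angles_deg <- as.numeric(angles_deg)
  if (length(angles_deg) != nrow(values)) {
    stop("one angle per sinogram row is required")
  }
  if (length(angles_deg) > 1 && any(diff(angles_deg) <= 0)) {
    stop("angles must be strictly increasing")
  }
  if (diff(range(angles_deg)) >= 360) stop("angles must span less than 360 degrees")
  structure(list(values = values, angles_deg = angles_deg,
                 detector_spacing = as.numeric(detector_spacing),
                 mu_ref = as.numeric(mu_ref)),
            class = "sinogram")
}

#' @export
dim.sinogram <- function(x) dim(x$values)

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d views x %d bins, detector pitch %.3g mm\n",
              nrow(x$values), ncol(x$values), x$detector_spacing))
  invisible(x)
}

#' Acquisition / projection geometry
#'
#' Uniformly spaced views over 180 degrees and a detector sized to cover
#' the grid diagonal of a reference image.
#'
#' @param image `ct_image` the geometry should cover.
#' @param views number of views m over `[0, 180)`.
#' @param bins number of detector bins; default covers the grid diagonal.
#' @param detector_spacing bin pitch in mm; default = min pixel spacing.
#' @param mu_ref water attenuation (1/cm) used for HU <-> mu scaling.
#' @return list with `angles_deg`, `bins`, `detector_spacing`, `mu_ref`.
#' @export
proj_geometry <- function(image, views = 360, bins = NULL,
                          detector_spacing = NULL, mu_ref = 0.2) {
  if (views < 2) stop("need at least 2 views")
  detector_spacing <- detector_spacing %||% min(image$pixel_spacing)
  if (is.null(bins)) {
    d <- dim(image$values)
    diag_mm <- sqrt(sum((d * image$pixel_spacing)^2))
    bins <- 2L * ceiling(diag_mm / detector_spacing / 2) + 1L
  }
  if (bins < 2) stop("need at least 2 detector bins")
  list(angles_deg = seq(0, 180, length.out = views + 1)[seq_len(views)],
       bins = as.integer(bins), detector_spacing = detector_spacing,
       mu_ref = mu_ref)
}

# Line integrals of a raw matrix (values integrated in 1/cm * cm units).
project_matrix <- function(mat, geometry, pixel_spacing, step_frac = 0.5) {
  cpp_forward_project(mat, geometry$angles_deg, geometry$bins,
                      geometry$detector_spacing, pixel_spacing[1],
                      pixel_spacing[2], step_frac)
}

#' Forward projection of an HU image
#'
#' Parallel-beam line integrals of the image after HU-to-attenuation
#' scaling `mu = mu_ref * (1 + HU/1000)` (clipped at zero). With
#' `scale = "raw"` the pixel values are integrated as-is (used e.g. to turn
#' a binary metal mask into metal path lengths).
#'
#' @param image a `ct_image`.
#' @param geometry from [proj_geometry()] (defaults to one built from the
#'   image).
#' @param scale `"mu"` (HU scaling) or `"raw"`.
#' @return a `sinogram`.
#' @export
forward_project <- function(image, geometry = proj_geometry(image),
                            scale = c("mu", "raw")) {
  scale <- match.arg(scale)
  mat <- if (scale == "mu") {
    pmax(geometry$mu_ref * (1 + image$values / 1000), 0)
  } else {
    image$values
  }
  sinogram(project_matrix(mat, geometry, image$pixel_spacing),
           geometry$angles_deg, geometry$detector_spacing,
           mu_ref = geometry$mu_ref)
}

# Frequency-domain ramp filter built from the band-limited spatial kernel
# (unit sample spacing), optionally apodised.
fbp_filter <- function(n, filter = c("ramp", "shepp-logan", "hann")) {
  filter <- match.arg(filter)
  stopifnot(n %% 2 == 0)
  f <- numeric(n)
  k <- c(seq(1, n / 2, 2), seq(n / 2 - 1, 1, -2) * -1)  # wrapped odd lags
  f[1] <- 0.25
  f[1 + which(seq_len(n - 1) %% 2 == 1)] <- -1 / (pi * abs(k))^2
  H <- 2 * Re(fft(f))
  freq <- c(seq(0, n / 2 - 1), seq(-n / 2, -1)) / n  # cycles/sample
  if (filter == "shepp-logan") {
    w <- pi * freq
    s <- rep(1, n); s[-1] <- sin(w[-1]) / w[-1]
    H <- H * s
  } else if (filter == "hann") {
    H <- H * (1 + cos(2 * pi * freq)) / 2
  }
  H
}

#' Filtered back projection
#'
#' Reconstructs an image from a parallel-beam sinogram: per-view ramp
#' filtering (with optional Shepp-Logan or Hann apodisation) in the Fourier
#' domain, pixel-driven backprojection, and inversion of the HU scaling
#' used by [forward_project()].
#'
#' @param sino a `sinogram`.
#' @param filter apodisation: `"ramp"`, `"shepp-logan"` or `"hann"`.
#' @param grid_shape output (rows, cols); default square grid spanned by
#'   the detector.
#' @param pixel_spacing output spacing in mm; default = detector spacing.
#' @param output `"hu"` (default) or `"mu"` (1/cm).
#' @return a `ct_image` (values clipped to its bit-depth range only when
#'   they exceed the extended representable range).
#' @export
fbp <- function(sino, filter = c("ramp", "shepp-logan", "hann"),
                grid_shape = NULL, pixel_spacing = NULL,
                output = c("hu", "mu")) {
  filter <- match.arg(filter)
  output <- match.arg(output)
  if (nrow(sino$values) < 2) stop("need at least 2 views")
  n <- ncol(sino$values)
  pad <- max(64L, 2L^ceiling(log2(2L * n)))
  H <- fbp_filter(pad, filter)
  P <- t(sino$values)
  Ppad <- rbind(P, matrix(0, pad - n, ncol(P)))
  Pf <- Re(mvfft(mvfft(Ppad) * H, inverse = TRUE)) / pad
  Pf <- t(Pf[seq_len(n), , drop = FALSE])
  if (is.null(pixel_spacing)) {
    pixel_spacing <- rep(sino$detector_spacing, 2)
  }
  pixel_spacing <- rep_len(pixel_spacing, 2L)
  if (is.null(grid_shape)) {
    side <- floor(n * sino$detector_spacing / sqrt(2) / max(pixel_spacing))
    grid_shape <- c(side, side)
  }
  grid_shape <- rep_len(as.integer(grid_shape), 2L)
  bp <- cpp_back_project(Pf, sino$angles_deg, sino$detector_spacing,
                         grid_shape[1], grid_shape[2], pixel_spacing[1],
                         pixel_spacing[2])
  # pi/(2 m) angular quadrature; divide by detector pitch (cm) to undo the
  # unit-spacing convention of the discrete ramp kernel.
  mu <- bp * pi / (2 * length(sino$angles_deg)) / (sino$detector_spacing / 10)
  vals <- if (output == "mu") mu else 1000 * (mu / sino$mu_ref - 1)
  ct_image(vals, pixel_spacing = pixel_spacing)
}

#' Metal trace in the sinogram domain
#'
#' Forward-projects the binary metal mask and flags every bin whose metal
#' path length exceeds `epsilon` (default: half the pixel diagonal, which
#' suppresses single-ray grazing bins). Per-view runs of flagged bins are
#' extracted as segments `[jj+1, jj+delta]` whose boundary bins `jj` and
#' `jj+delta+1` lie outside the trace.
#'
#' @param metal a `metal_mask` (see [segment_metal()]) or a `ct_image`
#'   holding a 0/1 metal indicator.
#' @param geometry from [proj_geometry()].
#' @param pixel_spacing (row, col) spacing in mm of the mask's grid; taken
#'   from the mask when it carries one.
#' @param epsilon minimum metal path length (cm) to flag a bin.
#' @return object of class `trace_mask`: logical `mask` (views x bins) and
#'   a data frame `segments` with columns `view`, `first`, `last`.
#' @export
metal_trace <- function(metal, geometry, pixel_spacing = NULL,
                        epsilon = NULL) {
  if (inherits(metal, "metal_mask")) {
    mask_mat <- metal$mask * 1
    pixel_spacing <- pixel_spacing %||% metal$pixel_spacing
  } else {
    mask_mat <- (metal$values != 0) * 1
    pixel_spacing <- pixel_spacing %||% metal$pixel_spacing
  }
  if (is.null(pixel_spacing)) stop("pixel_spacing is required")
  pixel_spacing <- rep_len(pixel_spacing, 2L)
  epsilon <- epsilon %||% (0.5 * sqrt(sum(pixel_spacing^2)) / 10)
  paths <- project_matrix(mask_mat, geometry, pixel_spacing)
  trace_from_mask(paths > epsilon)
}

# Build a trace_mask (mask + per-view segments) from a logical matrix.
trace_from_mask <- function(mask) {
  segs <- lapply(seq_len(nrow(mask)), function(v) {
    r <- rle(mask[v, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(view = v, first = starts[keep], last = ends[keep])
  })
  segs <- do.call(rbind, segs) %||%
    data.frame(view = integer(), first = integer(), last = integer())
  structure(list(mask = mask, segments = segs), class = "trace_mask")
}

#' @export
print.trace_mask <- function(x, ...) {
  cat(sprintf("<trace_mask> %d/%d bins flagged, %d segments\n",
              sum(x$mask), length(x$mask), nrow(x$segments)))
  invisible(x)
}

#' Boundary-continuous metal-trace replacement
#'
#' Replaces the metal trace of the measured kV sinogram with the prior
#' image's surrogate projections. Inside each per-view segment
#' `[jj+1, jj+delta]` the corrected value is the prior value plus a linear
#' blend of the two boundary offsets,
#' \deqn{P^{cor}_b = P^{prior}_b + \frac{(jj+\Delta+1-b)\,(P^{KV}_{jj} -
#'   P^{prior}_{jj}) + (b-jj)\,(P^{KV}_{jj+\Delta+1} -
#'   P^{prior}_{jj+\Delta+1})}{\Delta+1},}
#' so the corrected sinogram joins the measured data continuously at both
#' segment ends. Bins outside the trace are left bit-identical. A segment
#' touching the detector edge (no boundary bin on one side) falls back to a
#' one-sided constant offset and is counted in the `edge_segments`
#' attribute.
#'
#' @param p_kv measured (uncorrected) kV `sinogram`.
#' @param p_prior prior-image `sinogram` on the same geometry.
#' @param trace a `trace_mask` aligned with both sinograms.
#' @return corrected `sinogram`; attribute `edge_segments` counts one-sided
#'   segments.
#' @export
replace_trace <- function(p_kv, p_prior, trace) {
  if (!identical(dim(p_kv$values), dim(p_prior$values)) ||
      !identical(dim(p_kv$values), dim(trace$mask))) {
    stop("sinograms and trace are not aligned")
  }
  n <- ncol(p_kv$values)
  out <- p_kv$values
  edge <- 0L
  segs <- trace$segments
  for (i in seq_len(nrow(segs))) {
    v <- segs$view[i]; first <- segs$first[i]; last <- segs$last[i]
    jj <- first - 1L; jr <- last + 1L
    b <- first:last
    has_l <- jj >= 1L; has_r <- jr <= n
    if (has_l && has_r) {
      dl <- p_kv$values[v, jj] - p_prior$values[v, jj]
      dr <- p_kv$values[v, jr] - p_prior$values[v, jr]
      delta <- last - first + 1L
      off <- ((jr - b) * dl + (b - jj) * dr) / (delta + 1)
    } else if (has_l) {
      off <- p_kv$values[v, jj] - p_prior$values[v, jj]
      edge <- edge + 1L
    } else if (has_r) {
      off <- p_kv$values[v, jr] - p_prior$values[v, jr]
      edge <- edge + 1L
    } else {
      off <- 0
      edge <- edge + 1L
    }
    out[v, b] <- p_prior$values[v, b] + off
  }
  res <- sinogram(out, p_kv$angles_deg, p_kv$detector_spacing,
                  mu_ref = p_kv$mu_ref)
  attr(res, "edge_segments") <- edge
  res
}

#' Re-insert the segmented metal into a reconstruction
#'
#' @param reconstruction `ct_image` from FBP of the corrected sinogram.
#' @param metal_source `ct_image` supplying HU inside the metal (typically
#'   the registered pseudo-kV MV image), or a single HU value.
#' @param metal a `metal_mask` on the same grid.
#' @return `ct_image` equal to `reconstruction` outside the mask and to
#'   `metal_source` inside it.
#' @export
reinsert_metal <- function(reconstruction, metal_source, metal) {
  vals <- reconstruction$values
  if (is.numeric(metal_source) && length(metal_source) == 1) {
    vals[metal$mask] <- metal_source
  } else {
    check_same_grid(reconstruction, metal_source, "reconstruction and metal source")
    vals[metal$mask] <- metal_source$values[metal$mask]
  }
  ct_image(vals, pixel_spacing = reconstruction$pixel_spacing,
           origin = reconstruction$origin,
           bit_depth_range = reconstruction$bit_depth_range)
}
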
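#' MAR pipeline configuration
#'
#' Collects every tunable of the correction pipeline with its default.
#'
#' @param threshold_hu metal segmentation threshold (HU).
#' @param r_lo,r_hi deviation-weight ramp (see [deviation_weight()]).
#' @param sigma_mm distance-weight Gaussian sigma (mm).
#' @param fill_hu HU written into the metal region of the prior.
#' @param filter FBP apodisation.
#' @param views projection views over 180 degrees.
#' @param trace_epsilon minimum metal path length (cm) flagging a trace
#'   bin; `NULL` = half the pixel diagonal.
#' @param mu_ref water attenuation (1/cm) for HU <-> mu scaling.
#' @param metal_hu `"mv"` (re-insert MV HU values) or a fixed HU value.
#' @param calibration optional `calibration_curve` applied to the MV image.
#' @param register logical: rigid-register the MV image onto the kV grid
#'   (inputs from the simulator are already co-registered).
#' @param register_args list of extra arguments for [rigid_register()].
#' @return a list of class `mar_config`.
#' @export
mar_config <- function(threshold_hu = 3000, r_lo = 0.05, r_hi = 0.40,
                       sigma_mm = 30, fill_hu = 0, filter = "hann",
                       views = 360, trace_epsilon = NULL, mu_ref = 0.2,
                       metal_hu = "mv", calibration = NULL,
                       register = FALSE, register_args = list()) {
  structure(list(threshold_hu = threshold_hu, r_lo = r_lo, r_hi = r_hi,
                 sigma_mm = sigma_mm, fill_hu = fill_hu, filter = filter,
                 views = views, trace_epsilon = trace_epsilon,
                 mu_ref = mu_ref, metal_hu = metal_hu,
                 calibration = calibration, register = register,
                 register_args = register_args),
            class = "mar_config")
}

#' Dual-energy fusion MAR correction
#'
#' The full pipeline: calibrate the MV image to pseudo-kV HU, optionally
#' rigid-register it onto the kV grid, segment metal on the MV image, fuse
#' the two modalities into a prior (metal replaced by tissue), forward
#' project the prior, replace the kV sinogram's metal trace with
#' boundary-continuous surrogate data, reconstruct by FBP, and re-insert
#' the metal.
#'
#' @param i_kv uncorrected kV `ct_image`.
#' @param i_mv co-registered MV `ct_image` (raw MV HU if a calibration
#'   curve is configured, pseudo-kV otherwise).
#' @param config a [mar_config()].
#' @param kv_sinogram optional measured kV `sinogram`; when `NULL` the kV
#'   image is forward projected (the only option for image-only input).
#' @return list of class `mar_result`: `corrected` plus all intermediates
#'   (`mv_pseudo`, `metal`, `weights`, `fused`, `prior`, `p_kv`, `p_prior`,
#'   `p_cor`, `trace`, `recon`, `geometry`, `used_measured_sinogram`).
#' @export
mar_correct <- function(i_kv, i_mv, config = mar_config(),
                        kv_sinogram = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  mv <- stage("calibrate", {
    if (!is.null(config$calibration)) {
      apply_calibration(i_mv, config$calibration)
    } else i_mv
  })
  if (config$register) {
    mv <- stage("register", {
      if (!identical(dim(mv$values), dim(i_kv$values))) {
        mv <- resample_to_grid(mv, i_kv)
      }
      do.call(rigid_register,
              c(list(moving = mv, fixed = i_kv,
                     metal_threshold = config$threshold_hu),
                config$register_args))$registered
    })
  }
  metal <- stage("segment", segment_metal(mv, config$threshold_hu))
  geom <- proj_geometry(i_kv, views = config$views, mu_ref = config$mu_ref)
  if (!is.null(kv_sinogram)) {
    geom$angles_deg <- kv_sinogram$angles_deg
    geom$bins <- ncol(kv_sinogram$values)
    geom$detector_spacing <- kv_sinogram$detector_spacing
    geom$mu_ref <- kv_sinogram$mu_ref
  }
  if (!any(metal$mask)) {
    # degenerate no-metal case: nothing to replace
    p_kv <- stage("project", kv_sinogram %||% forward_project(i_kv, geom))
    recon <- stage("fbp", fbp(p_kv, filter = config$filter,
                              grid_shape = dim(i_kv$values),
                              pixel_spacing = i_kv$pixel_spacing))
    return(structure(list(corrected = recon, recon = recon, mv_pseudo = mv,
                          metal = metal, weights = NULL, fused = NULL,
                          prior = NULL, p_kv = p_kv, p_prior = NULL,
                          p_cor = p_kv, trace = NULL, geometry = geom,
                          used_measured_sinogram = !is.null(kv_sinogram)),
                     class = "mar_result"))
  }
  wts <- stage("fuse", {
    r <- relative_deviation(i_kv, mv)
    w <- deviation_weight(r, config$r_lo, config$r_hi)
    w_d <- distance_weight(metal, config$sigma_mm)
    list(r = r, w = w, w_d = w_d)
  })
  fused <- stage("fuse", fuse(i_kv, mv, wts$w, wts$w_d))
  prior <- stage("prior", make_prior(fused, metal, config$fill_hu))
  p_kv <- stage("project", kv_sinogram %||% forward_project(i_kv, geom))
  p_prior <- stage("project", forward_project(prior, geom))
  trace <- stage("trace", metal_trace(metal, geom,
                                      pixel_spacing = i_kv$pixel_spacing,
                                      epsilon = config$trace_epsilon))
  p_cor <- stage("replace", replace_trace(p_kv, p_prior, trace))
  recon <- stage("fbp", fbp(p_cor, filter = config$filter,
                            grid_shape = dim(i_kv$values),
                            pixel_spacing = i_kv$pixel_spacing))
  corrected <- stage("reinsert", {
    src <- if (identical(config$metal_hu, "mv")) mv else config$metal_hu
    reinsert_metal(recon, src, metal)
  })
  structure(list(corrected = corrected, recon = recon, mv_pseudo = mv,
                 metal = metal, weights = wts, fused = fused, prior = prior,
                 p_kv = p_kv, p_prior = p_prior, p_cor = p_cor,
                 trace = trace, geometry = geom,
                 used_measured_sinogram = !is.null(kv_sinogram)),
            class = "mar_result")
}

#' @export
print.mar_result <- function(x, ...) {
  cat("<mar_result>\n  corrected: "); print(x$corrected)
  if (!is.null(x$trace)) { cat("  trace: "); print(x$trace) }
  invisible(x)
}

# Linear interpolation across trace segments of a raw projection matrix,
# independent of replace_trace (LIMAR's own route).
interp_trace_linear <- function(values, trace) {
  n <- ncol(values)
  out <- values
  segs <- trace$segments
  for (i in seq_len(nrow(segs))) {
    v <- segs$view[i]; first <- segs$first[i]; last <- segs$last[i]
    jj <- first - 1L; jr <- last + 1L
    b <- first:last
    if (jj >= 1L && jr <= n) {
      delta <- last - first + 1L
      out[v, b] <- ((jr - b) * values[v, jj] + (b - jj) * values[v, jr]) /
        (delta + 1)
    } else if (jj >= 1L) {
      out[v, b] <- values[v, jj]
    } else if (jr <= n) {
      out[v, b] <- values[v, jr]
    }
  }
  out
}

#' LIMAR baseline: linear sinogram interpolation
#'
#' Replaces each per-view trace segment of the kV sinogram by the straight
#' line between its boundary bins, reconstructs by FBP, and re-inserts the
#' metal from the kV image's own thresholded values. Uses only the kV
#' data, so structure inside the trace (e.g. the air hole in the metal) is
#' unrecoverable.
#'
#' @param i_kv uncorrected kV `ct_image`.
#' @param metal optional `metal_mask`; default thresholds `i_kv` at
#'   `config$threshold_hu`.
#' @param config a [mar_config()].
#' @param kv_sinogram optional measured kV `sinogram`.
#' @param reinsert re-insert segmented metal into the output.
#' @return list of class `mar_result` (`corrected`, `recon`, `p_cor`,
#'   `trace`, ...).
#' @export
limar <- function(i_kv, metal = NULL, config = mar_config(),
                  kv_sinogram = NULL, reinsert = TRUE) {
  metal <- metal %||% segment_metal(i_kv, config$threshold_hu)
  geom <- proj_geometry(i_kv, views = config$views, mu_ref = config$mu_ref)
  if (!is.null(kv_sinogram)) {
    geom$angles_deg <- kv_sinogram$angles_deg
    geom$bins <- ncol(kv_sinogram$values)
    geom$detector_spacing <- kv_sinogram$detector_spacing
    geom$mu_ref <- kv_sinogram$mu_ref
  }
  p_kv <- kv_sinogram %||% forward_project(i_kv, geom)
  if (!any(metal$mask)) {
    recon <- fbp(p_kv, filter = config$filter, grid_shape = dim(i_kv$values),
                 pixel_spacing = i_kv$pixel_spacing)
    return(structure(list(corrected = recon, recon = recon, metal = metal,
                          p_kv = p_kv, p_cor = p_kv, trace = NULL,
                          geometry = geom),
                     class = "mar_result"))
  }
  trace <- metal_trace(metal, geom, pixel_spacing = i_kv$pixel_spacing,
                       epsilon = config$trace_epsilon)
  p_cor <- sinogram(interp_trace_linear(p_kv$values, trace),
                    p_kv$angles_deg, p_kv$detector_spacing,
                    mu_ref = p_kv$mu_ref)
  recon <- fbp(p_cor, filter = config$filter, grid_shape = dim(i_kv$values),
               pixel_spacing = i_kv$pixel_spacing)
  corrected <- if (reinsert) reinsert_metal(recon, i_kv, metal) else recon
  structure(list(corrected = corrected, recon = recon, metal = metal,
                 p_kv = p_kv, p_cor = p_cor, trace = trace, geometry = geom),
            class = "mar_result")
}

#' NMAR baseline: normalised sinogram interpolation
#'
#' Divides the kV sinogram by the prior's sinogram (floored at `epsilon`),
#' linearly interpolates the normalised trace segments, multiplies back,
#' reconstructs and re-inserts metal. With the tissue-class prior built
#' from a LIMAR pre-correction ([nmar_prior()]) this is the classic NMAR
#' baseline; with the registered pseudo-kV MV image as `prior` it is
#' NMAR-MV.
#'
#' @param i_kv uncorrected kV `ct_image`.
#' @param metal a `metal_mask` (on the kV grid).
#' @param prior prior `ct_image` (forward projected internally), or a
#'   `sinogram` of the prior supplied directly.
#' @param config a [mar_config()].
#' @param epsilon floor applied to the prior's projections before the
#'   division.
#' @param kv_sinogram optional measured kV `sinogram`.
#' @param metal_source image supplying re-inserted metal HU (default
#'   `i_kv`).
#' @return list of class `mar_result`.
#' @export
nmar <- function(i_kv, metal, prior, config = mar_config(),
                 epsilon = 1e-3, kv_sinogram = NULL, metal_source = i_kv) {
  geom <- proj_geometry(i_kv, views = config$views, mu_ref = config$mu_ref)
  if (!is.null(kv_sinogram)) {
    geom$angles_deg <- kv_sinogram$angles_deg
    geom$bins <- ncol(kv_sinogram$values)
    geom$detector_spacing <- kv_sinogram$detector_spacing
    geom$mu_ref <- kv_sinogram$mu_ref
  }
  p_kv <- kv_sinogram %||% forward_project(i_kv, geom)
  if (!any(metal$mask)) {
    recon <- fbp(p_kv, filter = config$filter, grid_shape = dim(i_kv$values),
                 pixel_spacing = i_kv$pixel_spacing)
    return(structure(list(corrected = recon, recon = recon, metal = metal,
                          p_kv = p_kv, p_cor = p_kv, trace = NULL,
                          geometry = geom),
                     class = "mar_result"))
  }
  p_prior <- if (inherits(prior, "sinogram")) prior else
    forward_project(prior, geom)
  if (!identical(dim(p_prior$values), dim(p_kv$values))) {
    stop("prior sinogram is not aligned with the kV sinogram")
  }
  trace <- metal_trace(metal, geom, pixel_spacing = i_kv$pixel_spacing,
                       epsilon = config$trace_epsilon)
  den <- pmax(p_prior$values, epsilon)
  p_norm <- p_kv$values / den
  p_norm_i <- interp_trace_linear(p_norm, trace)
  p_cor <- sinogram(p_norm_i * den, p_kv$angles_deg, p_kv$detector_spacing,
                    mu_ref = p_kv$mu_ref)
  recon <- fbp(p_cor, filter = config$filter, grid_shape = dim(i_kv$values),
               pixel_spacing = i_kv$pixel_spacing)
  corrected <- reinsert_metal(recon, metal_source, metal)
  structure(list(corrected = corrected, recon = recon, metal = metal,
                 prior = prior, p_kv = p_kv, p_prior = p_prior,
                 p_cor = p_cor, trace = trace, geometry = geom),
            class = "mar_result")
}

#' Tissue-class prior for NMAR
#'
#' Segments a LIMAR pre-correction (before metal re-insertion) into air
#' (< -500 HU), soft tissue (-500 to 500 HU) and bone (>= 500 HU, kept
#' as-is); air and soft tissue are set to their class means.
#'
#' @param limar_recon `ct_image`, the LIMAR reconstruction without metal
#'   re-inserted.
#' @param air_hu,soft_hu class boundaries.
#' @return prior `ct_image`.
#' @export
nmar_prior <- function(limar_recon, air_hu = -500, soft_hu = 500) {
  v <- limar_recon$values
  out <- v
  air <- v < air_hu
  soft <- v >= air_hu & v < soft_hu
  if (any(air)) out[air] <- mean(v[air])
  if (any(soft)) out[soft] <- mean(v[soft])
  ct_image(out, pixel_spacing = limar_recon$pixel_spacing,
           origin = limar_recon$origin,
           bit_depth_range = limar_recon$bit_depth_range)
}

#' NMAR-MV: NMAR with the MV image as prior
#'
#' The registered pseudo-kV MV image is used directly as the prior (metal
#' kept in it, which is what lets the normalisation carry the hole
#' structure through the trace); the metal mask and re-inserted HU come
#' from the MV image.
#'
#' @param i_kv uncorrected kV `ct_image`.
#' @param i_mv_pseudo calibrated, registered MV `ct_image`.
#' @param config a [mar_config()].
#' @param kv_sinogram optional measured kV `sinogram`.
#' @param epsilon prior-projection floor.
#' @return list of class `mar_result`.
#' @export
nmar_mv <- function(i_kv, i_mv_pseudo, config = mar_config(),
                    kv_sinogram = NULL, epsilon = 1e-3) {
  metal <- segment_metal(i_mv_pseudo, config$threshold_hu)
  nmar(i_kv, metal, i_mv_pseudo, config = config, epsilon = epsilon,
       kv_sinogram = kv_sinogram, metal_source = i_mv_pseudo)
}

#' Run all four MAR methods on one kV/MV pair
#'
#' Convenience wrapper running fusion MAR, LIMAR, NMAR and NMAR-MV with a
#' shared configuration.
#'
#' @inheritParams mar_correct
#' @return named list of `mar_result`s
#'   (`fusion`, `limar`, `nmar`, `nmar_mv`).
#' @export
run_mar_methods <- function(i_kv, i_mv, config = mar_config(),
                            kv_sinogram = NULL) {
  fusion <- mar_correct(i_kv, i_mv, config, kv_sinogram = kv_sinogram)
  li <- limar(i_kv, config = config, kv_sinogram = kv_sinogram)
  prior <- nmar_prior(li$recon)
  nm <- nmar(i_kv, li$metal, prior, config = config,
             kv_sinogram = kv_sinogram)
  nmmv <- nmar_mv(i_kv, fusion$mv_pseudo, config = config,
                  kv_sinogram = kv_sinogram)
  list(fusion = fusion, limar = li, nmar = nm, nmar_mv = nmmv)
}
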
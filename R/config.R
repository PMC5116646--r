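# Pipeline configuration: a single YAML file with one block per stage.
# Unknown keys are rejected; defaults are materialised so the resolved
# config echoed to the output directory fully reproduces a run.

pipeline_defaults <- function() {
  list(
    simulator = list(
      phantom = "metal-default",     # or path to a phantom fixture (unused here)
      grid = c(256L, 256L),
      pixel_spacing = c(1.18, 1.18),
      views = 360L,
      kv_photons = 1e5,
      mv_photons = 400,
      mv_blur_sigma = 1.5,
      seed = 1L
    ),
    calibration = list(
      curve = "fit-from-simulation", # or path to a two-column CSV
      n_rods = 5L
    ),
    fusion = list(
      threshold_hu = 3000,
      r_lo = 0.05,
      r_hi = 0.40,
      sigma_mm = 30,
      fill_hu = 0
    ),
    mar = list(
      method = "fusion",             # fusion | limar | nmar | nmar-mv
      filter = "hann",
      views = 360L,
      trace_epsilon = NULL,
      mu_ref = 0.2,
      use_measured_sinogram = TRUE
    ),
    evaluation = list(
      band_halfwidth_mm = 5,
      margin_mm = 2
    )
  )
}

#' Read and resolve a pipeline configuration
#'
#' Reads a YAML file, rejects unknown keys, and materialises every default
#' so the resolved configuration is self-contained.
#'
#' @param path YAML file; `NULL` returns pure defaults.
#' @return nested list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- pipeline_defaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  check_keys <- function(u, d, where) {
    bad <- setdiff(names(u), names(d))
    if (length(bad)) {
      stop("unknown configuration key(s) in ", where, ": ",
           paste(bad, collapse = ", "))
    }
    for (k in names(u)) {
      if (is.list(d[[k]]) && !is.null(names(d[[k]]))) {
        check_keys(u[[k]] %||% list(), d[[k]], paste0(where, "$", k))
      }
    }
  }
  check_keys(user, defaults, "config")
  cfg <- modifyList(defaults, user)
  structure(cfg, class = "pipeline_config")
}

write_resolved_config <- function(config, dir) {
  yaml::write_yaml(unclass(config), file.path(dir, "resolved_config.yaml"))
}

check_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    stop("output directory ", out_dir,
         " is not empty; use force = TRUE (--force) to overwrite")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
}

config_acquisitions <- function(config) {
  s <- config$simulator
  list(kv = kv_acquisition(views = s$views, incident_photons = s$kv_photons),
       mv = mv_acquisition(views = s$views, incident_photons = s$mv_photons,
                           detector_blur_sigma = s$mv_blur_sigma))
}

#' Simulate command: write truth, kV and MV artifacts
#'
#' Runs the scanner simulator on the configured phantom and writes five
#' artifacts (truth, kV image, MV image, kV sinogram, MV sinogram) plus a
#' manifest with the seed and a parameter hash to `out_dir`.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory.
#' @param force overwrite a non-empty output directory.
#' @return invisibly, the manifest list.
#' @export
cmd_simulate <- function(config, out_dir, force = FALSE) {
  check_out_dir(out_dir, force)
  s <- config$simulator
  spec <- if (identical(s$phantom, "metal-default")) {
    default_phantom()
  } else if (file.exists(s$phantom)) {
    read_phantom_spec(s$phantom)
  } else {
    stop("phantom file not found: '", s$phantom,
         "' (use 'metal-default' for the built-in phantom)")
  }
  acq <- config_acquisitions(config)
  kv <- simulate_acquisition(spec, s$grid, s$pixel_spacing, acq$kv,
                             seed = s$seed)
  mv <- simulate_acquisition(spec, s$grid, s$pixel_spacing, acq$mv,
                             seed = s$seed + 1)
  write_ct_image(kv$truth, file.path(out_dir, "truth_kv"))
  write_ct_image(kv$image, file.path(out_dir, "kv"))
  write_ct_image(mv$image, file.path(out_dir, "mv"))
  write_sinogram(kv$sinogram, file.path(out_dir, "kv_sino"))
  write_sinogram(mv$sinogram, file.path(out_dir, "mv_sino"))
  manifest <- list(seed = s$seed,
                   param_hash = config_hash(config),
                   artifacts = c("truth_kv", "kv", "mv", "kv_sino", "mv_sino"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_resolved_config(config, out_dir)
  invisible(manifest)
}

config_hash <- function(config) {
  # order-stable digest of the resolved configuration (no external deps)
  s <- yaml::as.yaml(unclass(config))
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997 + 1)) %% 2147483647
}

#' Correct command: run a MAR method on a kV/MV pair
#'
#' Loads kV and MV image fixtures (and the kV sinogram when configured and
#' present), runs the configured method, and writes the corrected image,
#' intermediates, a stage log and the resolved config.
#'
#' @param config a `pipeline_config`.
#' @param kv_prefix,mv_prefix fixture prefixes of the input images.
#' @param out_dir output directory.
#' @param kv_sino_prefix optional fixture prefix of the measured kV
#'   sinogram.
#' @param calibration optional `calibration_curve`.
#' @param force overwrite a non-empty output directory.
#' @return invisibly, the `mar_result` (or the result list for the chosen
#'   method).
#' @export
cmd_correct <- function(config, kv_prefix, mv_prefix, out_dir,
                        kv_sino_prefix = NULL, calibration = NULL,
                        force = FALSE) {
  check_out_dir(out_dir, force)
  log_path <- file.path(out_dir, "stages.log")
  logln <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                             append = TRUE)
  read_input <- function(prefix, what) {
    tryCatch(read_ct_image(prefix),
             error = function(e) stop("cannot read ", what, " input '",
                                      prefix, "': ", conditionMessage(e)))
  }
  i_kv <- read_input(kv_prefix, "kV")
  method <- config$mar$method
  f <- config$fusion
  mcfg <- mar_config(threshold_hu = f$threshold_hu, r_lo = f$r_lo,
                     r_hi = f$r_hi, sigma_mm = f$sigma_mm,
                     fill_hu = f$fill_hu, filter = config$mar$filter,
                     views = config$mar$views,
                     trace_epsilon = config$mar$trace_epsilon,
                     mu_ref = config$mar$mu_ref, calibration = calibration)
  kv_sino <- NULL
  if (isTRUE(config$mar$use_measured_sinogram) && !is.null(kv_sino_prefix)) {
    kv_sino <- read_sinogram(kv_sino_prefix)
    logln("input: measured kV sinogram %s", kv_sino_prefix)
  } else {
    logln("input: kV sinogram synthesised by forward projection")
  }
  t0 <- proc.time()[3]
  if (method == "limar") {
    logln("method limar: MV input ignored")
    res <- limar(i_kv, config = mcfg, kv_sinogram = kv_sino)
  } else {
    i_mv <- read_input(mv_prefix, "MV")
    res <- switch(method,
      fusion = mar_correct(i_kv, i_mv, mcfg, kv_sinogram = kv_sino),
      nmar = {
        li <- limar(i_kv, config = mcfg, kv_sinogram = kv_sino)
        nmar(i_kv, li$metal, nmar_prior(li$recon), config = mcfg,
             kv_sinogram = kv_sino)
      },
      `nmar-mv` = {
        mv <- if (is.null(calibration)) i_mv else
          apply_calibration(i_mv, calibration)
        nmar_mv(i_kv, mv, config = mcfg, kv_sinogram = kv_sino)
      },
      stop("unknown MAR method '", method, "'"))
  }
  logln("method %s finished in %.1f s", method, proc.time()[3] - t0)
  write_ct_image(res$corrected, file.path(out_dir, "corrected"))
  if (!is.null(res$prior)) write_ct_image(res$prior, file.path(out_dir, "prior"))
  if (!is.null(res$p_cor)) write_sinogram(res$p_cor, file.path(out_dir, "p_cor"))
  if (!is.null(res$weights)) {
    write_matrix_tsv(res$weights$w, file.path(out_dir, "weight_w.tsv"))
    write_matrix_tsv(res$weights$w_d, file.path(out_dir, "weight_wd.tsv"))
  }
  write_resolved_config(config, out_dir)
  invisible(res)
}

#' Evaluate command: score a corrected image against a reference
#'
#' Writes the percentage-difference map, centre line profiles and the
#' region-metrics CSV.
#'
#' @param config a `pipeline_config`.
#' @param corrected_prefix,reference_prefix image fixture prefixes.
#' @param out_dir output directory.
#' @param force overwrite a non-empty output directory.
#' @return invisibly, the metrics data frame.
#' @export
cmd_evaluate <- function(config, corrected_prefix, reference_prefix,
                         out_dir, force = FALSE) {
  check_out_dir(out_dir, force)
  test <- read_ct_image(corrected_prefix)
  ref <- read_ct_image(reference_prefix)
  pd <- percent_diff_map(test, ref)
  write_matrix_tsv(pd, file.path(out_dir, "percent_diff.tsv"))
  write_profile_csv(line_profile(test, "horizontal"),
                    file.path(out_dir, "profile_horizontal.csv"))
  write_profile_csv(line_profile(test, "vertical"),
                    file.path(out_dir, "profile_vertical.csv"))
  regions <- standard_regions(default_phantom(), ref,
                              config$evaluation$band_halfwidth_mm,
                              config$evaluation$margin_mm)
  metrics <- region_metrics(test, ref, regions)
  write_metrics_csv(metrics, file.path(out_dir, "region_metrics.csv"))
  write_resolved_config(config, out_dir)
  invisible(metrics)
}

#' Compare command: all four MAR methods on a simulated pair
#'
#' Simulates the configured phantom, fits the calibration curve from a
#' simulated calibration scan, runs fusion MAR, LIMAR, NMAR and NMAR-MV,
#' and writes a joint region-metrics table.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory.
#' @param force overwrite a non-empty output directory.
#' @return invisibly, the joint metrics data frame.
#' @export
cmd_compare <- function(config, out_dir, force = FALSE) {
  check_out_dir(out_dir, force)
  s <- config$simulator
  spec <- default_phantom()
  acq <- config_acquisitions(config)
  kv <- simulate_acquisition(spec, s$grid, s$pixel_spacing, acq$kv,
                             seed = s$seed)
  mv <- simulate_acquisition(spec, s$grid, s$pixel_spacing, acq$mv,
                             seed = s$seed + 1)
  curve <- NULL
  if (identical(config$calibration$curve, "fit-from-simulation")) {
    curve <- simulate_calibration_curve(config)
  } else if (!is.null(config$calibration$curve)) {
    curve <- read_calibration(config$calibration$curve)
  }
  f <- config$fusion
  mcfg <- mar_config(threshold_hu = f$threshold_hu, r_lo = f$r_lo,
                     r_hi = f$r_hi, sigma_mm = f$sigma_mm,
                     fill_hu = f$fill_hu, filter = config$mar$filter,
                     views = config$mar$views,
                     trace_epsilon = config$mar$trace_epsilon,
                     mu_ref = config$mar$mu_ref, calibration = curve)
  kv_sino <- if (isTRUE(config$mar$use_measured_sinogram)) kv$sinogram
  res <- run_mar_methods(kv$image, mv$image, mcfg, kv_sinogram = kv_sino)
  regions <- standard_regions(spec, kv$truth,
                              config$evaluation$band_halfwidth_mm,
                              config$evaluation$margin_mm)
  rows <- list(cbind(method = "uncorrected",
                     region_metrics(kv$image, kv$truth, regions)))
  for (nm in names(res)) {
    write_ct_image(res[[nm]]$corrected, file.path(out_dir, nm))
    rows[[nm]] <- cbind(method = nm,
                        region_metrics(res[[nm]]$corrected, kv$truth, regions))
  }
  joint <- do.call(rbind, rows)
  write_metrics_csv(joint, file.path(out_dir, "compare_metrics.csv"))
  write_resolved_config(config, out_dir)
  invisible(joint)
}

# Fit the MV -> kV calibration curve from simulated calibration-phantom
# scans (noise-free beams at both qualities; rods measured and paired).
simulate_calibration_curve <- function(config) {
  s <- config$simulator
  spec <- calibration_phantom(config$calibration$n_rods)
  grid <- c(192L, 192L)
  sp <- rep(32 * 10 / 192, 2)   # 32 cm field of view
  kv <- simulate_acquisition(spec, grid, sp,
                             kv_acquisition(views = 240,
                                            incident_photons = Inf),
                             seed = s$seed)
  mv <- simulate_acquisition(spec, grid, sp,
                             mv_acquisition(views = 240,
                                            incident_photons = Inf,
                                            detector_blur_sigma = 0),
                             seed = s$seed)
  fit_calibration(measure_rod_pairs(spec, mv$image, kv$image))
}
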
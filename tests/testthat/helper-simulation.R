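# Shared seeded study: one kV + MV simulation of the default metal phantom
# at 256^2 (1.18 mm), a calibration curve fitted from a simulated rod
# phantom, and all four MAR methods. Computed lazily once per test run and
# reused by the phenomenology / end-to-end / baseline-ordering tests.

.study_cache <- new.env(parent = emptyenv())

study_conditions <- function() {
  if (!is.null(.study_cache$study)) return(.study_cache$study)
  spec <- default_phantom()
  grid <- c(256L, 256L)
  px <- c(1.18, 1.18)
  kv <- simulate_acquisition(spec, grid, px, kv_acquisition(), seed = 1)
  mv <- simulate_acquisition(spec, grid, px, mv_acquisition(), seed = 2)
  curve <- study_calibration(seed = 1)
  config <- mar_config(calibration = curve)
  methods <- run_mar_methods(kv$image, mv$image, config,
                             kv_sinogram = kv$sinogram)
  regions <- standard_regions(spec, kv$truth)
  .study_cache$study <- list(spec = spec, grid = grid, px = px, kv = kv,
                             mv = mv, curve = curve, config = config,
                             methods = methods, regions = regions)
  .study_cache$study
}

study_calibration <- function(seed = 1, n_rods = 5) {
  spec <- calibration_phantom(n_rods)
  grid <- c(160L, 160L)
  px <- rep(320 / 160, 2)
  kv <- simulate_acquisition(spec, grid, px,
                             kv_acquisition(views = 200,
                                            incident_photons = Inf),
                             seed = seed)
  mv <- simulate_acquisition(spec, grid, px,
                             mv_acquisition(views = 200,
                                            incident_photons = Inf,
                                            detector_blur_sigma = 0),
                             seed = seed)
  fit_calibration(measure_rod_pairs(spec, mv$image, kv$image))
}

band_mae <- function(image, truth, regions) {
  band <- regions$long_axis_band | regions$short_axis_band
  mean(abs(image$values[band] - truth$values[band]))
}

region_mean <- function(image, mask) mean(image$values[mask])
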
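# Two-term linear attenuation model per material:
#   mu(E) = density * (photo70 * (70/E)^3 + compton70 * kn_rel(E))   [1/cm]
# photo70 / compton70 are the photoelectric and Compton mass attenuation
# contributions (cm^2/g) at the 70 keV reference energy; kn_rel is the
# Klein-Nishina total cross-section normalised to 1 at 70 keV. Water is
# anchored at 0.20 cm^-1 at 70 keV; steel's large photoelectric term makes
# its kV attenuation an order of magnitude above its MV attenuation, which
# is what drives beam hardening and photon starvation in the simulator.

REF_KEV <- c(kV = 70, MV = 1000)

# Klein-Nishina total cross section per electron (arbitrary units).
klein_nishina <- function(energy_kev) {
  a <- energy_kev / 511
  (1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - log(1 + 2 * a) / a) +
    log(1 + 2 * a) / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2
}

kn_rel <- function(energy_kev) klein_nishina(energy_kev) / klein_nishina(70)

#' Material attenuation table
#'
#' The default material map used by phantoms: density in g/cm^3 and the two
#' attenuation-model coefficients. `steel` reproduces the strongly
#' energy-dependent attenuation of stainless steel (density 7.8 g/cm^3);
#' `air` has zero attenuation, so its HU is exactly -1000 at every energy.
#'
#' @return named list of material definitions.
#' @export
default_materials <- function() {
  list(
    air         = ct_material(0.0,  0.0,    0.0),
    lung        = ct_material(0.30, 0.010,  0.190),
    adipose     = ct_material(0.92, 0.009,  0.190),
    water       = ct_material(1.00, 0.010,  0.190),
    soft_tissue = ct_material(1.06, 0.0105, 0.190),
    bone        = ct_material(1.60, 0.030,  0.190),
    cortical    = ct_material(1.90, 0.035,  0.190),
    steel       = ct_material(7.80, 0.440,  0.165)
  )
}

#' @param density g/cm^3, >= 0 (0 is reserved for air/vacuum).
#' @param photo70 photoelectric mass attenuation at 70 keV, cm^2/g.
#' @param compton70 Compton mass attenuation at 70 keV, cm^2/g.
#' @rdname default_materials
#' @export
ct_material <- function(density, photo70, compton70) {
  if (density < 0) stop("density must be >= 0")
  structure(list(density = density, photo70 = photo70, compton70 = compton70),
            class = "ct_material")
}

#' Linear attenuation coefficient of a material
#'
#' @param mat a `ct_material`.
#' @param energy_kev photon energy in keV, > 0.
#' @return mu in 1/cm.
#' @export
material_mu <- function(mat, energy_kev) {
  if (any(energy_kev <= 0)) stop("energy must be > 0")
  mat$density * (mat$photo70 * (70 / energy_kev)^3 +
                   mat$compton70 * kn_rel(energy_kev))
}

mu_water <- function(energy_kev) {
  material_mu(default_materials()$water, energy_kev)
}

# HU of a material at a given energy, relative to water at that energy.
material_hu <- function(mat, energy_kev) {
  if (mat$density == 0) return(-1000)
  1000 * (material_mu(mat, energy_kev) / mu_water(energy_kev) - 1)
}

#' Convert an HU image to a linear attenuation map
#'
#' Non-metal pixels use the water-equivalent scaling
#' `mu = mu_water(E) * (1 + HU/1000)` (clipped at 0); pixels at or above the
#' metal threshold are assigned the metal material's model attenuation, so
#' that kV metal attenuation greatly exceeds MV metal attenuation.
#'
#' @param image a `ct_image`.
#' @param energy_kev photon energy in keV.
#' @param metal_threshold HU at or above which a pixel is treated as metal;
#'   `Inf` disables the metal branch.
#' @param metal_material `ct_material` used for metal pixels.
#' @return matrix of attenuation coefficients (1/cm), all >= 0.
#' @export
hu_to_mu <- function(image, energy_kev, metal_threshold = 3000,
                     metal_material = default_materials()$steel) {
  if (energy_kev <= 0) stop("energy must be > 0")
  hu <- image$values
  mu <- pmax(mu_water(energy_kev) * (1 + hu / 1000), 0)
  if (is.finite(metal_threshold)) {
    mu[hu >= metal_threshold] <- material_mu(metal_material, energy_kev)
  }
  mu
}
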
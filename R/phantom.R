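#' Phantom primitives
#'
#' Vector shape primitives for phantom specifications. Coordinates are
#' physical, in cm, with (0, 0) at the phantom (grid) centre; `x` grows to
#' the right (columns), `y` downwards (rows). `rotation` is degrees
#' counter-clockwise about the shape centre.
#'
#' @param center length-2 (x, y) in cm.
#' @param semi_axes length-2 (x, y) semi-axes in cm (ellipse).
#' @param radius radius in cm (circle).
#' @param half_size length-2 (x, y) half side lengths in cm (rectangle).
#' @param rotation degrees.
#' @param material material label (must exist in the phantom's material
#'   map).
#' @return a shape primitive (list with class `phantom_shape`).
#' @export
ellipse_shape <- function(center, semi_axes, rotation = 0, material) {
  stopifnot(length(center) == 2, length(semi_axes) == 2, all(semi_axes > 0))
  structure(list(type = "ellipse", center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 rotation = as.numeric(rotation), material = material),
            class = "phantom_shape")
}

#' @rdname ellipse_shape
#' @export
circle_shape <- function(center, radius, material) {
  stopifnot(radius > 0)
  ellipse_shape(center, c(radius, radius), 0, material)
}

#' @rdname ellipse_shape
#' @export
rect_shape <- function(center, half_size, rotation = 0, material) {
  stopifnot(length(center) == 2, length(half_size) == 2, all(half_size > 0))
  structure(list(type = "rect", center = as.numeric(center),
                 half_size = as.numeric(half_size),
                 rotation = as.numeric(rotation), material = material),
            class = "phantom_shape")
}

# Membership test of physical points (cm) in a primitive, vectorised.
inside_shape <- function(shape, x, y, scale = 1, margin = 0) {
  th <- -shape$rotation * pi / 180
  dx <- x - shape$center[1]; dy <- y - shape$center[2]
  u <- dx * cos(th) - dy * sin(th)
  v <- dx * sin(th) + dy * cos(th)
  if (shape$type == "ellipse") {
    a <- shape$semi_axes[1] * scale + margin
    b <- shape$semi_axes[2] * scale + margin
    (u / a)^2 + (v / b)^2 <= 1
  } else {
    a <- shape$half_size[1] * scale + margin
    b <- shape$half_size[2] * scale + margin
    abs(u) <= a & abs(v) <= b
  }
}

# Boundary sample points of a primitive (cm), for containment checks.
shape_boundary <- function(shape, n = 90) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-1]
  if (shape$type == "ellipse") {
    u <- shape$semi_axes[1] * cos(t); v <- shape$semi_axes[2] * sin(t)
  } else {
    sq <- pmax(abs(cos(t)), abs(sin(t)))
    u <- shape$half_size[1] * cos(t) / sq
    v <- shape$half_size[2] * sin(t) / sq
  }
  th <- shape$rotation * pi / 180
  cbind(x = shape$center[1] + u * cos(th) + v * sin(th),
        y = shape$center[2] - u * sin(th) + v * cos(th))
}

#' Phantom specification
#'
#' An ordered list of material shapes inside an outer body boundary. Later
#' shapes paint over earlier ones when rasterised. Construction validates
#' that every referenced material exists, that non-air densities are
#' positive, and that every shape lies inside the body.
#'
#' @param body a `phantom_shape` giving the outer boundary (its material is
#'   the background inside the body).
#' @param shapes list of `phantom_shape`s, topmost last.
#' @param materials named list of `ct_material`s.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(body, shapes = list(),
                         materials = default_materials()) {
  spec <- structure(list(body = body, shapes = shapes, materials = materials),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  labels <- vapply(c(list(spec$body), spec$shapes), `[[`, "", "material")
  missing <- setdiff(labels, names(spec$materials))
  if (length(missing)) {
    stop("unknown material label(s): ", paste(missing, collapse = ", "))
  }
  for (lab in labels) {
    m <- spec$materials[[lab]]
    if (lab != "air" && m$density <= 0) {
      stop("material '", lab, "' must have strictly positive density")
    }
  }
  for (sh in spec$shapes) {
    bp <- shape_boundary(sh)
    if (!all(inside_shape(spec$body, bp[, "x"], bp[, "y"], margin = 1e-9))) {
      stop("shape with material '", sh$material,
           "' does not lie inside the body boundary")
    }
  }
  invisible(spec)
}

#' The default metal phantom
#'
#' A water-equivalent circular body (26 cm diameter) holding an elliptical
#' stainless-steel insert (long axis 4.97 cm, short axis 3.58 cm, density
#' 7.8 g/cm^3) with a central cylindrical air hole of diameter 1.81 cm, plus
#' three bone rods away from the metal so that line profiles cross
#' high-density structures unaffected by artifacts. The steel ellipse's long
#' axis lies along x (image columns).
#'
#' @return a `phantom_spec`.
#' @export
default_phantom <- function() {
  phantom_spec(
    body = circle_shape(c(0, 0), 13, "water"),
    shapes = list(
      ellipse_shape(c(0, 0), c(4.97 / 2, 3.58 / 2), 0, "steel"),
      circle_shape(c(0, 0), 1.81 / 2, "air"),
      circle_shape(c(9.5, 0), 1.0, "bone"),
      circle_shape(c(-9.5, 0), 1.0, "bone"),
      circle_shape(c(0, 9.5), 1.0, "bone")
    )
  )
}

#' Density-rod calibration phantom
#'
#' A 30 cm water circle with `n_rods` tissue-like rods whose densities ramp
#' from lung-like to cortical-bone-like, arranged on a ring. Used to fit the
#' MV-to-kV HU calibration curve from paired rod measurements.
#'
#' @param n_rods number of rods, >= 2.
#' @return a `phantom_spec`; rod materials are labelled `rod_1 ... rod_n`
#'   in order of strictly increasing density.
#' @export
calibration_phantom <- function(n_rods = 5) {
  if (n_rods < 2) stop("need at least 2 rods to define a calibration curve")
  rod_r <- 1.25; ring_r <- 10
  if (2 * ring_r * sin(pi / n_rods) <= 2 * rod_r) {
    stop("cannot fit ", n_rods, " non-overlapping rods on the ring")
  }
  dens <- seq(0.30, 1.90, length.out = n_rods)
  photo <- seq(0.010, 0.035, length.out = n_rods)
  mats <- default_materials()
  shapes <- vector("list", n_rods)
  for (i in seq_len(n_rods)) {
    lab <- paste0("rod_", i)
    mats[[lab]] <- ct_material(dens[i], photo[i], 0.190)
    th <- 2 * pi * (i - 1) / n_rods
    shapes[[i]] <- circle_shape(c(ring_r * cos(th), ring_r * sin(th)),
                                rod_r, lab)
  }
  phantom_spec(body = circle_shape(c(0, 0), 15, "water"), shapes = shapes,
               materials = mats)
}

# Integer label map of the rasterised spec (index into material table);
# 0 = outside body (air). Pixel centres decide membership; topmost wins.
rasterize_labels <- function(spec, grid_shape, pixel_spacing) {
  grid_shape <- rep_len(as.integer(grid_shape), 2L)
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  y <- ((seq_len(grid_shape[1]) - 1) - (grid_shape[1] - 1) / 2) *
    pixel_spacing[1] / 10
  x <- ((seq_len(grid_shape[2]) - 1) - (grid_shape[2] - 1) / 2) *
    pixel_spacing[2] / 10
  bp <- shape_boundary(spec$body)
  half_h <- grid_shape[1] * pixel_spacing[1] / 20
  half_w <- grid_shape[2] * pixel_spacing[2] / 20
  if (max(abs(bp[, "x"])) > half_w || max(abs(bp[, "y"])) > half_h) {
    stop("body boundary exceeds the requested grid")
  }
  xg <- matrix(x, grid_shape[1], grid_shape[2], byrow = TRUE)
  yg <- matrix(y, grid_shape[1], grid_shape[2])
  labels <- c(spec$body$material,
              vapply(spec$shapes, `[[`, "", "material"))
  lab_idx <- match(labels, names(spec$materials))
  out <- matrix(0L, grid_shape[1], grid_shape[2])
  out[inside_shape(spec$body, xg, yg)] <- lab_idx[1]
  for (i in seq_along(spec$shapes)) {
    out[inside_shape(spec$shapes[[i]], xg, yg)] <- lab_idx[i + 1]
  }
  out
}

#' Rasterise a phantom to a ground-truth HU image
#'
#' Each pixel takes the HU of the topmost shape covering its centre, at the
#' requested beam quality (HU of each material relative to water at the
#' kV or MV reference energy). Pixels outside the body are air (-1000 HU).
#' This is the "theoretical CT image" against which corrections are scored.
#'
#' @param spec a `phantom_spec`.
#' @param grid_shape (rows, cols).
#' @param pixel_spacing (row, col) spacing in mm.
#' @param energy `"kV"` or `"MV"`.
#' @return a `ct_image`.
#' @export
rasterize <- function(spec, grid_shape = c(512, 512),
                      pixel_spacing = c(0.59, 0.59), energy = c("kV", "MV")) {
  energy <- match.arg(energy)
  e_kev <- REF_KEV[[energy]]
  labels <- rasterize_labels(spec, grid_shape, pixel_spacing)
  hu_tab <- vapply(spec$materials, material_hu, 0, energy_kev = e_kev)
  vals <- matrix(-1000, nrow(labels), ncol(labels))
  inb <- labels > 0L
  vals[inb] <- hu_tab[labels[inb]]
  ct_image(vals, pixel_spacing = rep_len(pixel_spacing, 2L))
}
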
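#' Serialise a phantom specification as YAML
#'
#' The schema mirrors the in-memory structure: a `body` block and a
#' `shapes` list (each with `type` = ellipse | rect, `center` (cm),
#' `semi_axes` / `half_size` (cm), `rotation` (degrees), `material`), and
#' a `materials` map of `density` (g/cm^3), `photo70` and `compton70`
#' (cm^2/g at 70 keV). Circles are stored as ellipses with equal
#' semi-axes. Round trips reproduce the spec exactly up to YAML's numeric
#' formatting.
#'
#' @param spec a `phantom_spec`.
#' @param path YAML file path.
#' @export
write_phantom_spec <- function(spec, path) {
  shape_to_list <- function(sh) {
    out <- list(type = sh$type, center = sh$center,
                rotation = sh$rotation, material = sh$material)
    if (sh$type == "ellipse") out$semi_axes <- sh$semi_axes
    else out$half_size <- sh$half_size
    out
  }
  yaml::write_yaml(list(
    body = shape_to_list(spec$body),
    shapes = lapply(spec$shapes, shape_to_list),
    materials = lapply(spec$materials, function(m) {
      list(density = m$density, photo70 = m$photo70,
           compton70 = m$compton70)
    })), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  list_to_shape <- function(l) {
    if (identical(l$type, "ellipse")) {
      ellipse_shape(unlist(l$center), unlist(l$semi_axes),
                    l$rotation %||% 0, l$material)
    } else if (identical(l$type, "rect")) {
      rect_shape(unlist(l$center), unlist(l$half_size),
                 l$rotation %||% 0, l$material)
    } else {
      stop("unknown shape type '", l$type, "' in ", path)
    }
  }
  mats <- lapply(x$materials, function(m) {
    ct_material(m$density, m$photo70, m$compton70)
  })
  phantom_spec(body = list_to_shape(x$body),
               shapes = lapply(x$shapes, list_to_shape),
               materials = mats)
}
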
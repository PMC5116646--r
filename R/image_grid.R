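#' CT image grid
#'
#' A 2D CT slice in Hounsfield units together with its pixel geometry: the
#' common currency of every image-domain operation in the package. The
#' physical position of pixel `[r, c]` (centre) is
#' `origin + (c(r, c) - 1) * pixel_spacing`, in mm, with row coordinates
#' growing downwards and column coordinates to the right.
#'
#' @param values numeric matrix of HU (water = 0, air = -1000); must be
#'   finite.
#' @param pixel_spacing length-2 numeric, (row, col) spacing in mm, > 0.
#' @param origin length-2 numeric, physical (row, col) position in mm of the
#'   centre of pixel `[1, 1]`. The default centres the grid on (0, 0).
#' @param bit_depth_range length-2 numeric, representable HU range. The
#'   standard 12-bit CT range is `c(-1024, 3071)`; the default extended
#'   16-bit range accommodates metal HU above 3071.
#' @return an object of class `ct_image`.
#' @export
ct_image <- function(values, pixel_spacing = c(1, 1), origin = NULL,
                     bit_depth_range = c(-32768, 32767)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("image values must be finite")
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  if (any(pixel_spacing <= 0)) stop("pixel_spacing components must be > 0")
  if (is.null(origin)) {
    origin <- -(dim(values) - 1) / 2 * pixel_spacing
  }
  bit_depth_range <- as.numeric(bit_depth_range)
  if (bit_depth_range[1] > -1024 || bit_depth_range[2] < 3071) {
    stop("bit_depth_range must contain the standard CT range (-1024, 3071)")
  }
  structure(list(values = values, pixel_spacing = pixel_spacing,
                 origin = as.numeric(origin),
                 bit_depth_range = bit_depth_range),
            class = "ct_image")
}

#' @export
dim.ct_image <- function(x) dim(x$values)

#' @export
as.matrix.ct_image <- function(x, ...) x$values

#' @export
print.ct_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_image> %d x %d px, spacing %.3g x %.3g mm, HU [%.0f, %.0f]\n",
              d[1], d[2], x$pixel_spacing[1], x$pixel_spacing[2],
              min(x$values), max(x$values)))
  invisible(x)
}

# Physical coordinates (mm) of every pixel centre.
grid_coords <- function(image) {
  d <- dim(image$values)
  list(y = image$origin[1] + (seq_len(d[1]) - 1) * image$pixel_spacing[1],
       x = image$origin[2] + (seq_len(d[2]) - 1) * image$pixel_spacing[2])
}

# Same-grid check used by the pixel-wise operations.
check_same_grid <- function(a, b, what = "images") {
  if (!identical(dim(a$values), dim(b$values))) {
    stop(sprintf("%s are not aligned: dimensions differ", what))
  }
  if (max(abs(a$pixel_spacing - b$pixel_spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-6) {
    stop(sprintf("%s are not aligned: grids differ", what))
  }
  invisible(TRUE)
}

# Vectorised bilinear sampling of a matrix at fractional (row, col) indices
# (1-based). Out-of-field points take `fill`.
bilinear_sample <- function(values, r, c, fill = -1000) {
  nr <- nrow(values); nc <- ncol(values)
  out <- rep(fill, length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc & is.finite(r) & is.finite(c)
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * nr + r0
  v <- values[i00] * (1 - fr) * (1 - fc) + values[i00 + 1] * fr * (1 - fc) +
    values[i00 + nr] * (1 - fr) * fc + values[i00 + nr + 1] * fr * fc
  out[ok] <- v
  out
}

#' Resample an image onto the grid of another
#'
#' Bilinear resampling in physical coordinates: each pixel centre of the
#' target grid is mapped into the moving image's index space and sampled.
#' Pixels falling outside the moving image's field of view are filled with
#' air (-1000 HU).
#'
#' @param moving `ct_image` to be resampled.
#' @param target `ct_image` whose grid defines the output.
#' @param fill HU value for out-of-field pixels.
#' @return a `ct_image` on the target grid.
#' @export
resample_to_grid <- function(moving, target, fill = -1000) {
  tc <- grid_coords(target)
  xy <- expand.grid(y = tc$y, x = tc$x)
  r <- (xy$y - moving$origin[1]) / moving$pixel_spacing[1] + 1
  c <- (xy$x - moving$origin[2]) / moving$pixel_spacing[2] + 1
  vals <- bilinear_sample(moving$values, r, c, fill = fill)
  ct_image(matrix(vals, nrow = length(tc$y)),
           pixel_spacing = target$pixel_spacing, origin = target$origin,
           bit_depth_range = moving$bit_depth_range)
}

# Separable Gaussian convolution with replicated edges; sigma in pixels
# (length 2: row, col). Kernel truncated at 4 sigma.
gaussian_blur_px <- function(mat, sigma) {
  sigma <- rep_len(sigma, 2L)
  blur1 <- function(m, s, along_rows) {
    if (s <= 0) return(m)
    rad <- max(1L, ceiling(4 * s))
    k <- exp(-0.5 * ((-rad:rad) / s)^2)
    k <- k / sum(k)
    if (along_rows) m <- t(m)
    n <- ncol(m)
    idx <- c(rep(1L, rad), seq_len(n), rep(n, rad))
    mp <- m[, idx, drop = FALSE]
    out <- matrix(0, nrow(m), n)
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[, j:(j + n - 1), drop = FALSE]
    }
    if (along_rows) t(out) else out
  }
  blur1(blur1(mat, sigma[1], along_rows = TRUE), sigma[2], along_rows = FALSE)
}

# --- portable plain-text fixture I/O -------------------------------------

#' Write / read an image fixture
#'
#' Portable plain-text array format: `<prefix>.tsv` holds the matrix at full
#' double precision and `<prefix>.json` the grid metadata, so a write/read
#' round trip is bit-exact.
#'
#' @param image a `ct_image`.
#' @param prefix file path without extension.
#' @return `write_ct_image` returns the prefix invisibly; `read_ct_image`
#'   returns a `ct_image`.
#' @export
write_ct_image <- function(image, prefix) {
  write_matrix_tsv(image$values, paste0(prefix, ".tsv"))
  meta <- list(kind = "ct_image", pixel_spacing = image$pixel_spacing,
               origin = image$origin, bit_depth_range = image$bit_depth_range)
  jsonlite::write_json(meta, paste0(prefix, ".json"), digits = NA,
                       auto_unbox = FALSE)
  invisible(prefix)
}

#' @rdname write_ct_image
#' @export
read_ct_image <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (!identical(meta$kind, "ct_image")) stop("not a ct_image fixture: ", prefix)
  ct_image(read_matrix_tsv(paste0(prefix, ".tsv")),
           pixel_spacing = meta$pixel_spacing, origin = meta$origin,
           bit_depth_range = meta$bit_depth_range)
}

write_matrix_tsv <- function(m, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(apply(m, 1, function(row) {
    paste(sprintf("%.17g", row), collapse = "\t")
  }), con)
}

read_matrix_tsv <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = FALSE,
                            colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}
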
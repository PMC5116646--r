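#' Write / read a sinogram fixture
#'
#' Same portable plain-text format as [write_ct_image()]: values as TSV at
#' full precision, geometry (angles, detector pitch, mu reference) in a
#' JSON sidecar; round trips are bit-exact.
#'
#' @param sino a `sinogram`.
#' @param prefix file path without extension.
#' @export
write_sinogram <- function(sino, prefix) {
  write_matrix_tsv(sino$values, paste0(prefix, ".tsv"))
  meta <- list(kind = "sinogram", angles_deg = sino$angles_deg,
               detector_spacing = sino$detector_spacing,
               mu_ref = sino$mu_ref)
  jsonlite::write_json(meta, paste0(prefix, ".json"), digits = NA,
                       auto_unbox = FALSE)
  invisible(prefix)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (!identical(meta$kind, "sinogram")) stop("not a sinogram fixture: ", prefix)
  sinogram(read_matrix_tsv(paste0(prefix, ".tsv")),
           angles_deg = meta$angles_deg,
           detector_spacing = meta$detector_spacing, mu_ref = meta$mu_ref)
}
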
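#' Camera image with acquisition metadata
#'
#' A `nanosep_image` is an integer matrix of camera counts (rows = y,
#' columns = x) carrying the acquisition metadata every downstream stage
#' needs: pixel size, emission wavelength, numerical aperture, camera gain
#' and a channel label.
#'
#' @param counts Numeric matrix of non-negative camera counts.
#' @param pixel_size_nm Pixel size in nm.
#' @param wavelength_nm Emission wavelength in nm (may be `NA`).
#' @param numerical_aperture Objective NA (may be `NA`).
#' @param gain Camera gain, counts/photon.
#' @param channel Channel label, e.g. `"A"`.
#' @return A `nanosep_image`.
#' @export
nanosep_image <- function(counts, pixel_size_nm, wavelength_nm = NA_real_,
                          numerical_aperture = NA_real_, gain = 1,
                          channel = NA_character_) {
  if (!is.matrix(counts)) {
    nanosep_abort("`counts` must be a matrix.", "nanosep_domain_error")
  }
  if (any(counts < 0)) {
    nanosep_abort("Image counts must be non-negative.", "nanosep_domain_error")
  }
  structure(
    round(counts),
    class = c("nanosep_image", "matrix", "array"),
    pixel_size_nm = as.numeric(pixel_size_nm),
    wavelength_nm = as.numeric(wavelength_nm),
    numerical_aperture = as.numeric(numerical_aperture),
    gain = as.numeric(gain),
    channel = as.character(channel)
  )
}

#' @export
print.nanosep_image <- function(x, ...) {
  cat(sprintf(
    "<nanosep_image> %d x %d px (pixel %g nm, lambda %g nm, NA %g, gain %g, channel %s)\n",
    ncol(x), nrow(x), attr(x, "pixel_size_nm"), attr(x, "wavelength_nm"),
    attr(x, "numerical_aperture"), attr(x, "gain"), attr(x, "channel")))
  cat(sprintf("  counts: min %d, max %d, median %g\n",
              min(x), max(x), median(x)))
  invisible(x)
}

image_meta <- function(image) {
  list(
    pixel_size_nm = attr(image, "pixel_size_nm"),
    wavelength_nm = attr(image, "wavelength_nm"),
    numerical_aperture = attr(image, "numerical_aperture"),
    gain = attr(image, "gain"),
    channel = attr(image, "channel")
  )
}

image_spot_width <- function(image) {
  m <- image_meta(image)
  if (is.na(m$wavelength_nm) || is.na(m$numerical_aperture)) {
    nanosep_abort(
      "Image metadata lacks wavelength/NA; cannot derive the spot width.",
      "nanosep_metadata_error")
  }
  theoretical_width(m$wavelength_nm, m$numerical_aperture)
}

#' Write / read a 16-bit TIFF with a metadata sidecar
#'
#' Images are stored as single-channel 16-bit TIFF files. Acquisition
#' metadata travels in a small YAML sidecar (`<path>.yaml`) because TIFF
#' tags are an unreliable carrier for physical units.
#'
#' @param image A [nanosep_image()].
#' @param path Output TIFF path.
#' @return `write_image_tiff()` returns `path` invisibly; `read_image_tiff()`
#'   returns a [nanosep_image()].
#' @export
write_image_tiff <- function(image, path) {
  counts <- pmin(pmax(unclass(image), 0), 65535)
  writeTIFF(counts / 65535, path, bits.per.sample = 16, compression = "none")
  write_yaml(image_meta(image), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_image_tiff
#' @param metadata Optional named list overriding / replacing sidecar metadata.
#' @export
read_image_tiff <- function(path, metadata = NULL) {
  m <- readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  counts <- round(m * 65535)
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) read_yaml(side) else list()
  if (!is.null(metadata)) meta <- modifyList(meta, metadata)
  nanosep_image(
    counts,
    pixel_size_nm = meta$pixel_size_nm %||% NA_real_,
    wavelength_nm = meta$wavelength_nm %||% NA_real_,
    numerical_aperture = meta$numerical_aperture %||% NA_real_,
    gain = meta$gain %||% 1,
    channel = meta$channel %||% NA_character_
  )
}
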
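#' Frame geometry of a camera image
#'
#' Describes the pixel grid of an acquisition: the image dimensions and the
#' physical size of one camera pixel in the sample plane. All positions in
#' this package are reported in nanometers in the frame whose origin is the
#' top-left corner of pixel (0, 0); the center of pixel column `j`, row `i`
#' lies at `((j + 0.5) * pixel_size_nm, (i + 0.5) * pixel_size_nm)`. The
#' x axis runs along columns and the y axis along rows.
#'
#' @param width_px,height_px Integer image dimensions in pixels (>= 8).
#' @param pixel_size_nm Physical pixel size `a` in nm (> 0). The default,
#'   200 nm, matches a 63x objective on a conventional CCD.
#' @return A `frame_geometry` object.
#' @examples
#' frame_geometry(64, 64, 200)
#' @export
frame_geometry <- function(width_px, height_px, pixel_size_nm = 200) {
  if (!is.numeric(width_px) || !is.numeric(height_px) ||
      width_px < 8 || height_px < 8 ||
      width_px != round(width_px) || height_px != round(height_px)) {
    nanosep_abort("`width_px` and `height_px` must be integers >= 8.",
                  "nanosep_domain_error")
  }
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0) {
    nanosep_abort("`pixel_size_nm` must be > 0.", "nanosep_domain_error")
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         pixel_size_nm = as.numeric(pixel_size_nm)),
    class = "frame_geometry"
  )
}

#' @export
print.frame_geometry <- function(x, ...) {
  cat(sprintf("<frame_geometry> %d x %d px, pixel %g nm\n",
              x$width_px, x$height_px, x$pixel_size_nm))
  invisible(x)
}

#' Optical model of one imaging channel
#'
#' Emission wavelength and objective numerical aperture, from which the
#' diffraction-limited spot width follows (see [theoretical_width()]).
#'
#' @param wavelength_nm Emission wavelength lambda in nm (300-900).
#' @param numerical_aperture Objective NA (0 < NA <= 1.7).
#' @return An `optics_model` object.
#' @examples
#' optics_model(647, 1.45)
#' @export
optics_model <- function(wavelength_nm, numerical_aperture = 1.45) {
  if (!is.numeric(wavelength_nm) || wavelength_nm < 300 || wavelength_nm > 900) {
    nanosep_abort("`wavelength_nm` must lie in [300, 900].", "nanosep_domain_error")
  }
  if (!is.numeric(numerical_aperture) || numerical_aperture <= 0 ||
      numerical_aperture > 1.7) {
    nanosep_abort("`numerical_aperture` must lie in (0, 1.7].", "nanosep_domain_error")
  }
  structure(
    list(wavelength_nm = as.numeric(wavelength_nm),
         numerical_aperture = as.numeric(numerical_aperture)),
    class = "optics_model"
  )
}

#' @export
print.optics_model <- function(x, ...) {
  cat(sprintf("<optics_model> lambda %g nm, NA %g (s = %.1f nm)\n",
              x$wavelength_nm, x$numerical_aperture,
              theoretical_width(x$wavelength_nm, x$numerical_aperture)))
  invisible(x)
}

#' Camera and background noise model
#'
#' The camera model is: expected photons per pixel (uniform background `b`
#' plus the emitter contribution) -> Poisson shot noise -> multiply by gain
#' -> add Gaussian read noise -> round and clip at zero. Setting
#' `shot_noise = FALSE` with zero background and read noise yields the
#' deterministic expected image (useful as a fitting oracle).
#'
#' @param background_photons_per_px Uniform background `b` in photons/pixel (>= 0).
#' @param read_noise_e Gaussian read noise standard deviation in electrons
#'   (counts at unit gain) (>= 0).
#' @param gain_counts_per_photon Camera gain in counts/photon (> 0).
#' @param shot_noise Apply Poisson shot noise? Default `TRUE`.
#' @return A `noise_model` object.
#' @examples
#' noise_model(background_photons_per_px = 10, read_noise_e = 2)
#' noise_none()   # fully deterministic rendering
#' @export
noise_model <- function(background_photons_per_px = 0, read_noise_e = 0,
                        gain_counts_per_photon = 1, shot_noise = TRUE) {
  if (background_photons_per_px < 0 || read_noise_e < 0) {
    nanosep_abort("Background and read noise must be non-negative.",
                  "nanosep_domain_error")
  }
  if (gain_counts_per_photon <= 0) {
    nanosep_abort("`gain_counts_per_photon` must be > 0.", "nanosep_domain_error")
  }
  structure(
    list(background_photons_per_px = as.numeric(background_photons_per_px),
         read_noise_e = as.numeric(read_noise_e),
         gain_counts_per_photon = as.numeric(gain_counts_per_photon),
         shot_noise = isTRUE(shot_noise)),
    class = "noise_model"
  )
}

#' @rdname noise_model
#' @export
noise_none <- function() {
  noise_model(0, 0, 1, shot_noise = FALSE)
}

#' Theoretical width of a diffraction-limited spot
#'
#' Standard deviation `s` of the Gaussian approximation to the point spread
#' function: `s = 0.21 * lambda / NA`.
#'
#' @param wavelength_nm Emission wavelength in nm (> 0).
#' @param numerical_aperture Objective numerical aperture (> 0).
#' @return Width `s` in nm.
#' @examples
#' theoretical_width(650, 1.45)  # ~94.1 nm
#' @export
theoretical_width <- function(wavelength_nm, numerical_aperture) {
  if (any(wavelength_nm <= 0) || any(numerical_aperture <= 0)) {
    nanosep_abort("Wavelength and numerical aperture must be positive.",
                  "nanosep_domain_error")
  }
  0.21 * wavelength_nm / numerical_aperture
}

#' Default ROI half-width for a given spot size
#'
#' The ROI should include the spot "and a few pixels beyond": half-width
#' `ceiling(3 s / a) + 2` pixels, so a 200-nm pixel and a ~94-nm spot give
#' half-width 4 (a 9 x 9 ROI).
#'
#' @param s_nm Gaussian spot width in nm.
#' @param pixel_size_nm Pixel size in nm.
#' @return Integer half-width in pixels.
#' @export
default_half_width <- function(s_nm, pixel_size_nm) {
  as.integer(ceiling(3 * s_nm / pixel_size_nm) + 2L)
}
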
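#' Monte-Carlo batch of isolated spots, rendered and localized
#'
#' The calibration workhorse: renders `n` isolated spots at known sub-pixel
#' positions (uniform within +/- `offset_px` of the frame-center pixel
#' center), localizes each with the chosen estimator, and returns truth and
#' estimate side by side. Used to measure iteration counts, localization
#' RMSE against the precision formula, and the accuracy ordering of the
#' three estimators.
#'
#' @param n Number of spots.
#' @param photons Expected photons per spot.
#' @param background_photons Uniform background, photons/pixel.
#' @param seed Integer seed (one stream for the whole batch).
#' @param frame_px Side of the (square) rendering frame (default 15 px).
#' @param pixel_size_nm,wavelength_nm,numerical_aperture Acquisition
#'   parameters (defaults 200 nm, 650 nm, 1.45).
#' @param gain,read_noise_e Camera model (defaults 1, 0).
#' @param method `"lsq"`, `"centroid"` or `"mle"`.
#' @param offset_px True sub-pixel offset range (default 0.5, i.e. anywhere
#'   within the central pixel).
#' @param half_width_px ROI half-width (default from the optics).
#' @param ... Passed to the fitting function (e.g. `tol`).
#' @return Tibble with `true_x_nm`, `true_y_nm`, the localization columns
#'   of [localize_spots()], `error_x_nm`, `error_y_nm`, and the
#'   formula-predicted precision `sigma_pred_nm` computed from the true
#'   photon budget and background.
#' @export
simulate_spot_batch <- function(n, photons, background_photons = 0, seed = 1,
                                frame_px = 15, pixel_size_nm = 200,
                                wavelength_nm = 650, numerical_aperture = 1.45,
                                gain = 1, read_noise_e = 0,
                                method = c("lsq", "centroid", "mle"),
                                offset_px = 0.5, half_width_px = NULL, ...) {
  method <- match.arg(method)
  frame <- frame_geometry(frame_px, frame_px, pixel_size_nm)
  optics <- optics_model(wavelength_nm, numerical_aperture)
  noise <- noise_model(background_photons, read_noise_e, gain)
  s <- theoretical_width(wavelength_nm, numerical_aperture)
  a <- pixel_size_nm
  center_px <- frame_px %/% 2        # 0-based index of the central pixel
  cx <- (center_px + 0.5) * a
  with_seed(as.integer(seed), {
    offs <- matrix(runif(2 * n, -offset_px, offset_px) * a, ncol = 2)
    spot_seeds <- sample.int(.Machine$integer.max - 10L, n)
  })
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    x_true <- cx + offs[i, 1]; y_true <- cx + offs[i, 2]
    img <- render_image(tibble(x_nm = x_true, y_nm = y_true, photons = photons),
                        frame, optics, noise, seed = spot_seeds[i])
    row <- tryCatch({
      roi <- extract_roi(img, c(center_px, center_px), half_width_px)
      localize_one(roi, method, ...)
    }, nanosep_error = function(e) NULL)
    if (is.null(row)) next
    row$true_x_nm <- x_true
    row$true_y_nm <- y_true
    rows[[i]] <- row
  }
  out <- bind_rows(rows)
  out$error_x_nm <- out$x_nm - out$true_x_nm
  out$error_y_nm <- out$y_nm - out$true_y_nm
  out$sigma_pred_nm <- localization_precision(
    s, photons, a, sqrt(background_photons))
  out
}

#' Simulate perfectly colocalized two-color pairs at a stated precision
#'
#' The colocalization control: both channels see the same true positions;
#' each channel's localization carries independent isotropic Gaussian error
#' of `precision_nm` per axis. Channel-B apparent positions are
#' additionally displaced by the chromatic warp (if given), to be undone
#' by a registration model downstream.
#'
#' @param n_pairs Number of pairs.
#' @param precision_nm Per-channel, per-axis localization precision
#'   (default 15 nm, a typical per-peak value for faint FISH foci).
#' @param frame A [frame_geometry()] the positions are scattered over.
#' @param warp Optional [channel_warp()] applied to channel-B positions.
#' @param seed Integer seed.
#' @param margin_frac Fraction of the frame kept as margin (default 0.15,
#'   so positions stay inside a central region covered by fiducials).
#' @return List with `foci_a`, `foci_b` (tibbles with `pair_id`, `x_nm`,
#'   `y_nm`, `sigma_nm`) and `truth` (`pair_id`, true `x_nm`, `y_nm`).
#' @export
simulate_colocalized_pairs <- function(n_pairs, precision_nm = 15, frame,
                                       warp = NULL, seed = 1,
                                       margin_frac = 0.15) {
  a <- frame$pixel_size_nm
  xmax <- frame$width_px * a; ymax <- frame$height_px * a
  with_seed(as.integer(seed), {
    x <- runif(n_pairs, margin_frac * xmax, (1 - margin_frac) * xmax)
    y <- runif(n_pairs, margin_frac * ymax, (1 - margin_frac) * ymax)
    err <- matrix(rnorm(4 * n_pairs, 0, precision_nm), ncol = 4)
  })
  b_true <- tibble(x_nm = x, y_nm = y)
  if (!is.null(warp)) b_true <- apply_warp(warp, b_true)
  list(
    foci_a = tibble(pair_id = seq_len(n_pairs),
                    x_nm = x + err[, 1], y_nm = y + err[, 2],
                    sigma_nm = precision_nm),
    foci_b = tibble(pair_id = seq_len(n_pairs),
                    x_nm = b_true$x_nm + err[, 3],
                    y_nm = b_true$y_nm + err[, 4],
                    sigma_nm = precision_nm),
    truth = tibble(pair_id = seq_len(n_pairs), x_nm = x, y_nm = y)
  )
}
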
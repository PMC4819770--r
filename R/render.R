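#' Render synthetic micrographs of diffraction-limited spots
#'
#' The generator draws each emitter as a 2D Gaussian of standard deviation
#' `s = 0.21 lambda / NA` integrated over each camera pixel (an
#' error-function difference, not a point sample at the pixel center), adds
#' a uniform background, applies Poisson shot noise to photons, multiplies
#' by the camera gain, adds Gaussian read noise, and rounds/clips to
#' non-negative integer counts. With all noise off the rendered image is
#' the expected image, so total counts equal the emitter photon budget up
#' to truncation at the frame edge.
#'
#' @param emitters Data frame with columns `x_nm`, `y_nm`, `photons`
#'   (expected photons per emitter; positions in the frame coordinate
#'   convention of [frame_geometry()]).
#' @param frame A [frame_geometry()].
#' @param optics An [optics_model()] for the channel.
#' @param noise A [noise_model()].
#' @param seed Integer seed; identical seed and parameters give
#'   bit-identical images.
#' @param channel Channel label stored in the image metadata.
#' @return A [nanosep_image()].
#' @examples
#' fr <- frame_geometry(32, 32, 200)
#' op <- optics_model(650, 1.45)
#' img <- render_image(tibble::tibble(x_nm = 3200, y_nm = 3200, photons = 1000),
#'                     fr, op, noise_none(), seed = 1)
#' sum(img)  # ~1000
#' @export
render_image <- function(emitters, frame, optics, noise = noise_none(),
                         seed = 1, channel = NA_character_) {
  stopifnot(inherits(frame, "frame_geometry"), inherits(optics, "optics_model"),
            inherits(noise, "noise_model"))
  emitters <- as_tibble(emitters)
  if (nrow(emitters) > 0 && any(emitters$photons <= 0)) {
    nanosep_abort("Emitter photons must be positive.", "nanosep_domain_error")
  }
  s <- theoretical_width(optics$wavelength_nm, optics$numerical_aperture)
  a <- frame$pixel_size_nm
  W <- frame$width_px; H <- frame$height_px
  field <- matrix(0, nrow = H, ncol = W)
  if (nrow(emitters) > 0) {
    xe <- (0:W) * a   # pixel edges
    ye <- (0:H) * a
    for (k in seq_len(nrow(emitters))) {
      fx <- diff(pnorm(xe, mean = emitters$x_nm[k], sd = s))
      fy <- diff(pnorm(ye, mean = emitters$y_nm[k], sd = s))
      field <- field + emitters$photons[k] * outer(fy, fx)
    }
  }
  lambda <- field + noise$background_photons_per_px
  with_seed(as.integer(seed), {
    photons <- if (noise$shot_noise) {
      matrix(rpois(length(lambda), lambda), nrow = H)
    } else {
      lambda
    }
    counts <- photons * noise$gain_counts_per_photon
    if (noise$read_noise_e > 0) {
      counts <- counts + rnorm(length(counts), 0, noise$read_noise_e)
    }
  })
  counts <- pmin(pmax(round(counts), 0), 65535)
  nanosep_image(counts, pixel_size_nm = a,
                wavelength_nm = optics$wavelength_nm,
                numerical_aperture = optics$numerical_aperture,
                gain = noise$gain_counts_per_photon, channel = channel)
}

#' Render a single isolated spot
#'
#' Convenience wrapper over [render_image()] for one emitter. The emitter
#' must lie inside the frame with at least a `3 s` margin so the spot is
#' not clipped.
#'
#' @param emitter One-row data frame or named list with `x_nm`, `y_nm`,
#'   `photons`.
#' @inheritParams render_image
#' @return A [nanosep_image()].
#' @export
render_spot <- function(emitter, frame, optics, noise = noise_none(),
                        seed = 1, channel = NA_character_) {
  e <- as_tibble(as.list(emitter)[c("x_nm", "y_nm", "photons")])
  s <- theoretical_width(optics$wavelength_nm, optics$numerical_aperture)
  a <- frame$pixel_size_nm
  if (e$x_nm < 3 * s || e$x_nm > frame$width_px * a - 3 * s ||
      e$y_nm < 3 * s || e$y_nm > frame$height_px * a - 3 * s) {
    nanosep_abort("Emitter must lie inside the frame with a >= 3 s margin.",
                  "nanosep_position_error")
  }
  render_image(e, frame, optics, noise, seed, channel)
}

sample_isolated_positions <- function(n, frame, margin_nm, min_dist_nm,
                                      max_tries = 5000) {
  a <- frame$pixel_size_nm
  xmax <- frame$width_px * a; ymax <- frame$height_px * a
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0
  while (length(xs) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      nanosep_abort("Could not place isolated emitters; frame too crowded.",
                    "nanosep_domain_error")
    }
    x <- runif(1, margin_nm, xmax - margin_nm)
    y <- runif(1, margin_nm, ymax - margin_nm)
    if (length(xs) == 0 || all(sqrt((xs - x)^2 + (ys - y)^2) >= min_dist_nm)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  tibble(x_nm = xs, y_nm = ys)
}

#' Render a two-channel fiducial bead field
#'
#' Multispectral beads appear at the same true positions in both channels;
#' channel-B apparent positions are displaced by the chromatic warp. Beads
#' closer than `4 s` to each other are resampled, since downstream fitting
#' assumes isolated spots.
#'
#' @param n_beads Number of beads (>= 15: enough for a 12-fiducial model
#'   plus hold-outs).
#' @param warp A [channel_warp()] applied to channel-B positions.
#' @param frame A [frame_geometry()].
#' @param optics_a,optics_b Per-channel [optics_model()]s.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param bead_photons Expected photons per bead per channel (TetraSpeck
#'   beads are bright; default 20000).
#' @return A list with `image_a`, `image_b` ([nanosep_image()]s) and
#'   `truth`, a tibble with one row per bead: true position (common frame)
#'   and the warped channel-B apparent position.
#' @export
render_bead_field <- function(n_beads, warp, frame, optics_a, optics_b,
                              noise = noise_model(background_photons_per_px = 5),
                              seed = 1, bead_photons = 20000) {
  if (n_beads < 15) {
    nanosep_abort("`n_beads` must be >= 15 (12 fiducials plus hold-outs).",
                  "nanosep_domain_error")
  }
  s_max <- max(theoretical_width(optics_a$wavelength_nm, optics_a$numerical_aperture),
               theoretical_width(optics_b$wavelength_nm, optics_b$numerical_aperture))
  with_seed(as.integer(seed), {
    pos <- sample_isolated_positions(n_beads, frame,
                                     margin_nm = 4 * s_max,
                                     min_dist_nm = 4 * s_max)
  })
  warped <- apply_warp(warp, pos)
  truth <- tibble(
    bead_id = seq_len(n_beads),
    x_nm = pos$x_nm, y_nm = pos$y_nm,
    x_b_nm = warped$x_nm, y_b_nm = warped$y_nm,
    photons = bead_photons, seed = as.integer(seed)
  )
  list(
    image_a = render_image(tibble(x_nm = pos$x_nm, y_nm = pos$y_nm,
                                  photons = bead_photons),
                           frame, optics_a, noise, seed = seed + 1L,
                           channel = "A"),
    image_b = render_image(tibble(x_nm = warped$x_nm, y_nm = warped$y_nm,
                                  photons = bead_photons),
                           frame, optics_b, noise, seed = seed + 2L,
                           channel = "B"),
    truth = truth
  )
}

#' Render a two-color nucleus scene of transcription-focus pairs
#'
#' Each pair is a channel-A and a channel-B emitter a stated true distance
#' apart, emulating two-color RNA-FISH foci at nascent transcription sites.
#' Channel-B emitters are rendered at their warped (aberrated) positions;
#' the ground truth keeps both the common-frame positions and the true
#' separations so the full pipeline can be scored against them.
#'
#' @param pairs Data frame with one row per pair: `x_nm`, `y_nm` (pair
#'   midpoint), `separation_nm` (>= 0), optional `angle_rad` (separation
#'   axis; drawn uniformly when absent) and optional `photons_a`,
#'   `photons_b` (default `photons`).
#' @param photons Default expected photons per focus when the `pairs` table
#'   does not carry per-pair budgets.
#' @inheritParams render_bead_field
#' @return A list with `image_a`, `image_b` and a `truth` tibble in long
#'   (one row per rendered emitter) format.
#' @export
render_nucleus_scene <- function(pairs, frame, optics_a, optics_b,
                                 noise = noise_model(background_photons_per_px = 10),
                                 warp = NULL, seed = 1, photons = 150) {
  pairs <- as_tibble(pairs)
  if (any(pairs$separation_nm < 0)) {
    nanosep_abort("Separations must be >= 0.", "nanosep_domain_error")
  }
  s_max <- max(theoretical_width(optics_a$wavelength_nm, optics_a$numerical_aperture),
               theoretical_width(optics_b$wavelength_nm, optics_b$numerical_aperture))
  if (nrow(pairs) > 1) {
    dmat <- as.matrix(stats::dist(cbind(pairs$x_nm, pairs$y_nm)))
    diag(dmat) <- Inf
    if (min(dmat) < 8 * s_max) {
      nanosep_abort("Pairs overlap: pair midpoints must be >= 8 s apart.",
                    "nanosep_domain_error")
    }
  }
  if (is.null(warp)) warp <- warp_identity(frame)
  with_seed(as.integer(seed), {
    if (is.null(pairs[["angle_rad"]])) {
      pairs$angle_rad <- runif(nrow(pairs), 0, 2 * pi)
    }
  })
  if (is.null(pairs[["photons_a"]])) pairs$photons_a <- photons
  if (is.null(pairs[["photons_b"]])) pairs$photons_b <- photons
  half <- pairs$separation_nm / 2
  ax <- pairs$x_nm - half * cos(pairs$angle_rad)
  ay <- pairs$y_nm - half * sin(pairs$angle_rad)
  bx <- pairs$x_nm + half * cos(pairs$angle_rad)
  by <- pairs$y_nm + half * sin(pairs$angle_rad)
  b_app <- apply_warp(warp, tibble(x_nm = bx, y_nm = by))
  n <- nrow(pairs)
  truth <- bind_rows(
    tibble(pair_id = seq_len(n), channel = "A",
           x_nm = ax, y_nm = ay, x_apparent_nm = ax, y_apparent_nm = ay,
           photons = pairs$photons_a, true_separation_nm = pairs$separation_nm),
    tibble(pair_id = seq_len(n), channel = "B",
           x_nm = bx, y_nm = by,
           x_apparent_nm = b_app$x_nm, y_apparent_nm = b_app$y_nm,
           photons = pairs$photons_b, true_separation_nm = pairs$separation_nm)
  )
  truth$seed <- as.integer(seed)
  list(
    image_a = render_image(tibble(x_nm = ax, y_nm = ay, photons = pairs$photons_a),
                           frame, optics_a, noise, seed = seed + 1L, channel = "A"),
    image_b = render_image(tibble(x_nm = b_app$x_nm, y_nm = b_app$y_nm,
                                  photons = pairs$photons_b),
                           frame, optics_b, noise, seed = seed + 2L, channel = "B"),
    truth = truth
  )
}

#' Write a ground-truth table as TSV
#'
#' @param truth Ground-truth tibble from a renderer.
#' @param path Output TSV path.
#' @param scene_id Scene identifier recorded in the table.
#' @export
write_ground_truth <- function(truth, path, scene_id = 1L) {
  out <- as_tibble(truth)
  out$scene_id <- scene_id
  cols <- intersect(
    c("scene_id", "pair_id", "bead_id", "channel", "x_nm", "y_nm",
      "x_apparent_nm", "y_apparent_nm", "x_b_nm", "y_b_nm", "photons",
      "true_separation_nm", "seed"),
    names(out))
  write_tsv(out[, cols], path)
  invisible(path)
}
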
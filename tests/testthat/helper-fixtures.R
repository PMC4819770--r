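# Shared fixtures: canonical acquisition conditions (200-nm pixels,
# 63x/1.45 NA objective, red/far-red emission) and small builders used
# across the test files. Everything is generated in code at test time.

test_frame <- function(px = 32) frame_geometry(px, px, 200)
test_optics <- function(lambda = 650) optics_model(lambda, 1.45)
S_650 <- 0.21 * 650 / 1.45   # theoretical spot width at 650 nm / 1.45 NA

# wrap a bare counts matrix into an ROI with the canonical metadata
make_test_roi <- function(counts, anchor = c(x = 0, y = 0), gain = 1,
                          lambda = 650) {
  structure(
    list(counts = counts, anchor_px = anchor, pixel_size_nm = 200,
         wavelength_nm = lambda, numerical_aperture = 1.45,
         gain = gain, channel = "A"),
    class = "nanosep_roi")
}

# render one spot and hand back the centered ROI (image is 32 x 32)
spot_roi <- function(x_nm, y_nm, photons, noise = noise_none(), seed = 1,
                     frame = test_frame(), optics = test_optics()) {
  img <- render_image(tibble::tibble(x_nm = x_nm, y_nm = y_nm,
                                     photons = photons),
                      frame, optics, noise, seed = seed)
  center_px <- c(floor(x_nm / 200), floor(y_nm / 200))
  extract_roi(img, center_px, 4)
}

# noiseless fiducial truth table under a warp: columns match match_fiducials()
warped_truth_pairs <- function(n, warp, frame, seed = 1, margin_frac = 0.1) {
  a <- frame$pixel_size_nm
  lim_x <- frame$width_px * a; lim_y <- frame$height_px * a
  withr::with_seed(seed, {
    x <- runif(n, margin_frac * lim_x, (1 - margin_frac) * lim_x)
    y <- runif(n, margin_frac * lim_y, (1 - margin_frac) * lim_y)
  })
  b <- apply_warp(warp, tibble::tibble(x_nm = x, y_nm = y))
  tibble::tibble(x_a = x, y_a = y, x_b = b$x_nm, y_b = b$y_nm)
}

rmse <- function(x) sqrt(mean(x^2))
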
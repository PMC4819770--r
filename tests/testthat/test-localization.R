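test_that("initialization follows the brightest-pixel / perimeter rules", {
  m <- matrix(100, 9, 9); m[5, 5] <- 500
  init <- initial_estimate(make_test_roi(m), s_theory = 94.1)
  expect_equal(init$z0, 100)
  expect_equal(init$A, 400)
  expect_equal(init$x0, (4 + 0.5) * 200)   # center of 0-based pixel (4, 4)
  expect_equal(init$y0, (4 + 0.5) * 200)
  expect_equal(init$sx, 94.1)
  expect_equal(init$sy, 94.1)
  expect_equal(init$theta, 0)
  # ties break to the first maximum in row-major order
  m2 <- matrix(100, 9, 9); m2[3, 7] <- 500; m2[5, 5] <- 500
  init2 <- initial_estimate(make_test_roi(m2))
  expect_equal(init2$x0, (6 + 0.5) * 200)
  expect_equal(init2$y0, (2 + 0.5) * 200)
  # uniform ROI is un-fittable
  expect_error(initial_estimate(make_test_roi(matrix(7, 9, 9))),
               class = "nanosep_unfittable_error")
})

test_that("the fitted model evaluates to z0 + A at its peak", {
  roi <- spot_roi(3250, 3250, 5000)
  fit <- fit_gaussian_lsq(roi)
  expect_equal(predict(fit, fit$x0_nm, fit$y0_nm), fit$z0 + fit$A)
})

test_that("noiseless spots are recovered to sub-0.1-nm accuracy by LSQ", {
  for (pos in list(c(3265, 3142), c(3300, 3300), c(3180, 3395))) {
    fit <- fit_gaussian_lsq(spot_roi(pos[1], pos[2], 10000))
    expect_true(fit$converged)
    expect_lt(abs(fit$x0_nm - pos[1]), 0.1)
    expect_lt(abs(fit$y0_nm - pos[2]), 0.1)
  }
})

test_that("all three estimators agree on a noiseless pixel-centered spot", {
  # emitter exactly at a pixel center: the symmetric case where even the
  # binned centroid is exact
  roi <- spot_roi(3300, 3300, 10000)
  lsq <- fit_gaussian_lsq(roi)
  mle <- fit_gaussian_mle(roi)
  cen <- localize_centroid(roi)
  for (est in list(c(lsq$x0_nm, lsq$y0_nm), c(mle$x0_nm, mle$y0_nm),
                   c(cen$x_nm, cen$y_nm))) {
    expect_lt(abs(est[1] - 3300), 0.1)
    expect_lt(abs(est[2] - 3300), 0.1)
  }
})

test_that("the centroid tracks sub-pixel shifts of a noiseless spot", {
  base <- localize_centroid(spot_roi(3300, 3300, 10000))
  shifted <- localize_centroid(spot_roi(3300 + 60, 3300, 10000))  # 0.3 px
  expect_lt(abs((shifted$x_nm - base$x_nm) - 60) / 200, 0.05)
})

test_that("MLE improves the likelihood and matches LSQ on clean data", {
  roi <- spot_roi(3265, 3142, 10000)
  lsq <- fit_gaussian_lsq(roi)
  mle <- fit_gaussian_mle(roi)
  expect_true(mle$converged)
  expect_lte(mle$nll, mle$nll_init)   # ascent from the initial guess
  expect_lt(abs(mle$x0_nm - lsq$x0_nm), 0.1)
  expect_lt(abs(mle$y0_nm - lsq$y0_nm), 0.1)
})

test_that("photon counts are conserved and gain-invariant", {
  roi <- spot_roi(3300, 3300, 1000)
  fit <- fit_gaussian_lsq(roi)
  expect_lt(abs(fit$photons_N - 1000), 5)
  expect_lt(abs(fit$photons_N_model - 1000) / 1000, 0.05)
  # doubling the gain leaves the photon estimate unchanged
  roi2 <- spot_roi(3300, 3300, 1000,
                   noise = noise_model(0, 0, 2, shot_noise = FALSE))
  fit2 <- fit_gaussian_lsq(roi2)
  expect_lt(abs(fit2$photons_N - 1000) / 1000, 0.01)
  # background-only ROI: N ~ 0
  bg <- render_image(tibble::tibble(x_nm = numeric(0), y_nm = numeric(0),
                                    photons = numeric(0)),
                     test_frame(), test_optics(), noise_model(50), seed = 4)
  roi_bg <- extract_roi(bg, c(16, 16), 4)
  z0 <- mean(roi_bg$counts[c(1, 9), ])
  ph <- photons_from_counts(roi_bg, list(z0 = z0, A = 1, sx_nm = 94, sy_nm = 94))
  expect_lt(ph$N_photons, 100)  # ~0 against ~4000 background photons in the ROI
})

test_that("the precision formula matches hand-evaluated cases", {
  expect_equal(localization_precision(100, 1000, 200, 0),
               sqrt(10 + 200^2 / 12000), tolerance = 1e-9)
  expect_equal(localization_precision(100, 1000, 200, 0), 3.651, tolerance = 1e-3)
  expect_equal(localization_precision(100, 1000, 200, 10),
               sqrt(10 + 200^2 / 12000 + 2 * pi), tolerance = 1e-9)
  expect_equal(localization_precision(100, 1000, 200, 10), 4.429, tolerance = 1e-3)
  # more photons always help
  N <- c(100, 500, 2000, 10000)
  sig <- localization_precision(94, N, 200, 5)
  expect_true(all(diff(sig) < 0))
  expect_true(all(localization_precision(94, 2 * N, 200, 5) < sig))
  expect_error(localization_precision(94, 0, 200, 5),
               class = "nanosep_domain_error")
})

test_that("the in-house Levenberg-Marquardt agrees with an independent fitter", {
  roi <- spot_roi(3265, 3142, 3000, noise = noise_model(10), seed = 17)
  fit <- fit_gaussian_lsq(roi, tol = 1e-10)
  # same pixel-integrated objective handed to minpack.lm's optimizer
  g <- nanosep:::roi_grid(roi)
  df <- data.frame(z = as.vector(roi$counts))
  pred <- function(z0, A, x0, y0, sx, sy) {
    cc <- sqrt(2 * pi) / 200
    Gx <- cc * sx * diff(pnorm((g$xe - x0) / sx))
    Gy <- cc * sy * diff(pnorm((g$ye - y0) / sy))
    as.vector(z0 + A * outer(Gy, Gx))
  }
  ref <- minpack.lm::nlsLM(
    z ~ pred(z0, A, x0, y0, sx, sy), data = df,
    start = list(z0 = 10, A = max(roi$counts), x0 = 3250, y0 = 3150,
                 sx = 94, sy = 94),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12))
  cf <- coef(ref)
  expect_lt(abs(fit$x0_nm - cf[["x0"]]), 0.1)
  expect_lt(abs(fit$y0_nm - cf[["y0"]]), 0.1)
  expect_lt(abs(fit$sx_nm - cf[["sx"]]), 0.5)
})

test_that("convergence bookkeeping honors the tolerance definition", {
  roi <- spot_roi(3265, 3142, 5000, noise = noise_model(10), seed = 3)
  fit <- fit_gaussian_lsq(roi)
  expect_true(fit$converged)
  expect_lte(fit$n_iterations, 100)
  # a tighter tolerance can only need more iterations
  fit_tight <- fit_gaussian_lsq(roi, tol = 1e-8)
  expect_gte(fit_tight$n_iterations, fit$n_iterations)
  # parameter-step criterion is available
  fit_p <- fit_gaussian_lsq(roi, converge_on = "params")
  expect_true(fit_p$converged)
})

test_that("localize_spots assembles a full localization table", {
  fr <- frame_geometry(64, 64, 200)
  em <- tibble::tibble(x_nm = c(2500, 9700), y_nm = c(2900, 8300),
                       photons = 3000)
  img <- render_image(em, fr, test_optics(), noise_model(10), seed = 8)
  loc <- localize_spots(img)
  expect_equal(nrow(loc), 2)
  expect_true(all(c("x_nm", "y_nm", "sigma_nm", "N_photons", "converged",
                    "n_iterations", "method") %in% names(loc)))
  expect_true(all(loc$converged))
  ord <- order(loc$x_nm)
  expect_lt(max(abs(loc$x_nm[ord] - em$x_nm)), 10)
  expect_lt(max(abs(loc$y_nm[ord] - em$y_nm)), 10)
})
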
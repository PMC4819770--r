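#' Initial parameter estimate for a Gaussian spot fit
#'
#' Standard initialization: peak intensity from the brightest pixel,
#' background from the perimeter-pixel mean, position at the center of the
#' brightest pixel, both widths at the theoretical diffraction-limited
#' value, rotation zero. Ties for the brightest pixel break to the first in
#' row-major order, so initialization is deterministic.
#'
#' @param roi A `nanosep_roi` (should have passed QC).
#' @param s_theory Initial Gaussian width in nm; default `0.21 lambda / NA`
#'   from the ROI metadata.
#' @return A `fit_init` list: `z0`, `A` (counts), `x0`, `y0`, `sx`, `sy`
#'   (nm), `theta` (radians, 0).
#' @export
initial_estimate <- function(roi, s_theory = NULL) {
  if (is.null(s_theory)) s_theory <- roi_spot_width(roi)
  counts <- roi$counts
  z0 <- mean(roi_perimeter(counts))
  # row-major first occurrence of the maximum
  tm <- t(counts)
  idx <- which.max(tm)
  col <- ((idx - 1) %% nrow(tm)) + 1  # column in the original matrix
  row <- ((idx - 1) %/% nrow(tm)) + 1
  A <- counts[row, col] - z0
  if (A <= 0) {
    nanosep_abort("ROI has no intensity above background; un-fittable.",
                  "nanosep_unfittable_error")
  }
  g <- roi_grid(roi)
  structure(
    list(z0 = z0, A = A, x0 = g$xc[col], y0 = g$yc[row],
         sx = s_theory, sy = s_theory, theta = 0),
    class = "fit_init")
}

# Pixel-mean model and analytic Jacobian for the axis-aligned elliptical
# Gaussian z0 + A exp(-[((x-x0)/sx)^2 + ((y-y0)/sy)^2] / 2), integrated over
# each pixel (error-function differences). Returns the model matrix and,
# when `jacobian`, an n_px x 6 matrix with columns (z0, A, x0, y0, sx, sy).
gauss_model_integrated <- function(theta, grid, jacobian = FALSE) {
  z0 <- theta[1]; A <- theta[2]; x0 <- theta[3]; y0 <- theta[4]
  sx <- theta[5]; sy <- theta[6]
  cc <- sqrt(2 * pi) / grid$a
  ux <- (grid$xe - x0) / sx
  uy <- (grid$ye - y0) / sy
  Mx <- diff(pnorm(ux)); My <- diff(pnorm(uy))
  Gx <- cc * sx * Mx; Gy <- cc * sy * My
  shape <- outer(Gy, Gx)
  m <- z0 + A * shape
  if (!jacobian) return(list(m = m))
  phx <- dnorm(ux); phy <- dnorm(uy)
  dGx_dx0 <- -cc * diff(phx)
  dGy_dy0 <- -cc * diff(phy)
  dGx_dsx <- cc * (sx * Mx / sx) - cc * diff(phx * ux)  # = cc*(Mx - diff(phi*u))
  dGy_dsy <- cc * (sy * My / sy) - cc * diff(phy * uy)
  n <- length(m)
  J <- cbind(
    z0 = rep(1, n),
    A = as.vector(shape),
    x0 = as.vector(A * outer(Gy, dGx_dx0)),
    y0 = as.vector(A * outer(dGy_dy0, Gx)),
    sx = as.vector(A * outer(Gy, dGx_dsx)),
    sy = as.vector(A * outer(dGy_dsy, Gx))
  )
  list(m = m, J = J)
}

# point-sampled rotated Gaussian, numerical Jacobian (opt-in mode)
gauss_model_rotated <- function(theta, grid, jacobian = FALSE) {
  z0 <- theta[1]; A <- theta[2]; x0 <- theta[3]; y0 <- theta[4]
  sx <- theta[5]; sy <- theta[6]; th <- theta[7]
  X <- matrix(grid$xc, nrow = length(grid$yc), ncol = length(grid$xc),
              byrow = TRUE) - x0
  Y <- matrix(grid$yc, nrow = length(grid$yc), ncol = length(grid$xc)) - y0
  Xr <- cos(th) * X + sin(th) * Y
  Yr <- -sin(th) * X + cos(th) * Y
  m <- z0 + A * exp(-((Xr / sx)^2 + (Yr / sy)^2) / 2)
  if (!jacobian) return(list(m = m))
  eps <- pmax(abs(theta) * 1e-6, 1e-8)
  J <- sapply(seq_along(theta), function(j) {
    tp <- theta; tp[j] <- tp[j] + eps[j]
    as.vector((gauss_model_rotated(tp, grid)$m - m) / eps[j])
  })
  list(m = m, J = J)
}

#' Least-squares 2D Gaussian fit of a spot
#'
#' Fits the elliptical Gaussian-plus-background model
#' `F(x, y) = z0 + A exp(-[((x - x0)/sx)^2 + ((y - y0)/sy)^2] / 2)`
#' to the ROI counts by Levenberg-Marquardt iteration, minimizing the sum
#' of squared differences between the model (averaged over each pixel) and
#' the observed counts. The two widths adjust independently — lateral
#' symmetry is an initialization assumption, never a constraint. The fit
#' converges when the relative change of the residual sum of squares
#' between successive iterations falls below `tol` (default 1e-4, i.e.
#' 0.01%); an alternative parameter-step criterion is available via
#' `converge_on = "params"`.
#'
#' @param roi A `nanosep_roi`.
#' @param init A `fit_init` from [initial_estimate()]; computed if `NULL`.
#' @param tol Relative convergence tolerance (default `1e-4`).
#' @param max_iterations Iteration cap (default 100).
#' @param converge_on `"rss"` (relative change of the residual sum of
#'   squares, the default) or `"params"` (maximum relative parameter step).
#' @param rotated Opt-in rotated-Gaussian mode: adds a rotation angle
#'   `theta` and evaluates the model at pixel centers rather than as pixel
#'   means (the rotated profile does not integrate separably).
#' @return A `spot_fit`: fitted parameters (positions/widths in nm, counts
#'   for `z0`/`A`), `n_iterations`, `converged`, `residual_ss`, photon
#'   count `photons_N` (with the model-based cross-check
#'   `photons_N_model`), perimeter background noise `b_photons`, and the
#'   localization precision `sigma_nm`.
#' @seealso [localization_precision()], [fit_gaussian_mle()],
#'   [localize_centroid()]
#' @export
fit_gaussian_lsq <- function(roi, init = NULL, tol = 1e-4,
                             max_iterations = 100,
                             converge_on = c("rss", "params"),
                             rotated = FALSE) {
  converge_on <- match.arg(converge_on)
  if (is.null(init)) init <- initial_estimate(roi)
  grid <- roi_grid(roi)
  counts <- as.vector(roi$counts)
  model_fun <- if (rotated) gauss_model_rotated else gauss_model_integrated
  theta <- if (rotated) {
    c(init$z0, init$A, init$x0, init$y0, init$sx, init$sy, init$theta)
  } else {
    c(init$z0, init$A, init$x0, init$y0, init$sx, init$sy)
  }
  xr <- range(grid$xe); yr <- range(grid$ye)

  ss <- sum((as.vector(model_fun(theta, grid)$m) - counts)^2)
  lambda <- 1e-3
  n_iter <- 0L
  converged <- FALSE
  drifted <- FALSE
  while (n_iter < max_iterations) {
    mj <- model_fun(theta, grid, jacobian = TRUE)
    r <- as.vector(mj$m) - counts
    J <- mj$J
    g <- crossprod(J, r)
    H <- crossprod(J)
    accepted <- FALSE
    while (!accepted && lambda < 1e10 && n_iter < max_iterations) {
      n_iter <- n_iter + 1L
      Haug <- H + lambda * diag(pmax(diag(H), 1e-12))
      delta <- tryCatch(solve(Haug, -g), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      cand <- theta + as.vector(delta)
      if (cand[5] <= 1 || cand[6] <= 1) { lambda <- lambda * 10; next }
      ss_new <- sum((as.vector(model_fun(cand, grid)$m) - counts)^2)
      if (!is.finite(ss_new) || ss_new > ss) { lambda <- lambda * 10; next }
      accepted <- TRUE
      lambda <- max(lambda / 10, 1e-12)
      crit <- if (converge_on == "rss") {
        (ss - ss_new) / max(ss, .Machine$double.eps)
      } else {
        max(abs(cand - theta) / pmax(abs(theta), 1e-8))
      }
      theta <- cand
      ss <- ss_new
      if (crit < tol || ss == 0) converged <- TRUE
      if (n_iter >= max_iterations) break
    }
    if (theta[3] < xr[1] || theta[3] > xr[2] ||
        theta[4] < yr[1] || theta[4] > yr[2]) {
      drifted <- TRUE
      converged <- FALSE
      break
    }
    if (!accepted || converged) break
  }

  new_spot_fit(roi, theta, rotated, method = "lsq",
               n_iterations = n_iter, converged = converged && !drifted,
               drifted = drifted, residual_ss = ss)
}

new_spot_fit <- function(roi, theta, rotated, method, n_iterations,
                         converged, drifted, residual_ss) {
  gain <- roi$gain %||% 1
  fit <- structure(
    list(method = method,
         z0 = theta[1], A = theta[2],
         x0_nm = theta[3], y0_nm = theta[4],
         sx_nm = theta[5], sy_nm = theta[6],
         theta = if (rotated) theta[7] else 0,
         rotated = rotated,
         n_iterations = as.integer(n_iterations),
         converged = converged, drifted = drifted,
         residual_ss = residual_ss,
         anchor_px = roi$anchor_px,
         pixel_size_nm = roi$pixel_size_nm,
         gain = gain, channel = roi$channel),
    class = "spot_fit")
  ph <- photons_from_counts(roi, fit, gain)
  fit$photons_N <- ph$N_photons
  fit$photons_N_model <- ph$N_model
  fit$b_photons <- sd(roi_perimeter(roi$counts)) / gain
  fit$sigma_nm <- if (fit$photons_N > 0) {
    localization_precision(sqrt(fit$sx_nm * fit$sy_nm), fit$photons_N,
                           roi$pixel_size_nm, fit$b_photons)
  } else {
    NA_real_
  }
  fit
}

#' @export
print.spot_fit <- function(x, ...) {
  cat(sprintf(
    "<spot_fit:%s> (%.1f, %.1f) nm, sx %.1f sy %.1f nm, A %.0f z0 %.1f, N %.0f, sigma %.2f nm (%s in %d iter)\n",
    x$method, x$x0_nm, x$y0_nm, x$sx_nm, x$sy_nm, x$A, x$z0, x$photons_N,
    x$sigma_nm, if (x$converged) "converged" else "NOT converged",
    x$n_iterations))
  invisible(x)
}

# fitted model over an ROI, pixel-mean form used for the fit
predict_fit_matrix <- function(fit, roi) {
  grid <- roi_grid(roi)
  theta <- c(fit$z0, fit$A, fit$x0_nm, fit$y0_nm, fit$sx_nm, fit$sy_nm)
  if (isTRUE(fit$rotated)) {
    gauss_model_rotated(c(theta, fit$theta), grid)$m
  } else {
    gauss_model_integrated(theta, grid)$m
  }
}

#' Evaluate the fitted Gaussian profile at points
#'
#' Point evaluation of the continuous model
#' `F(x, y) = z0 + A exp(-[((x-x0)/sx)^2 + ((y-y0)/sy)^2]/2)`; at the peak
#' `(x0, y0)` this equals `z0 + A`.
#'
#' @param object A `spot_fit`.
#' @param x_nm,y_nm Coordinates in nm.
#' @param ... Unused.
#' @return Model intensities (counts).
#' @export
predict.spot_fit <- function(object, x_nm, y_nm, ...) {
  dx <- (x_nm - object$x0_nm) / object$sx_nm
  dy <- (y_nm - object$y0_nm) / object$sy_nm
  if (isTRUE(object$rotated) && object$theta != 0) {
    xr <- cos(object$theta) * (x_nm - object$x0_nm) +
      sin(object$theta) * (y_nm - object$y0_nm)
    yr <- -sin(object$theta) * (x_nm - object$x0_nm) +
      cos(object$theta) * (y_nm - object$y0_nm)
    dx <- xr / object$sx_nm; dy <- yr / object$sy_nm
  }
  object$z0 + object$A * exp(-(dx^2 + dy^2) / 2)
}

#' Background-subtracted centroid localization
#'
#' The simplest estimator: subtract the perimeter-mean background, clip
#' negative residuals to zero, and take the intensity-weighted centroid.
#' Reasonably accurate for bright spots, but degrades rapidly as
#' signal-to-noise falls, because noise in the ROI tails pulls the
#' centroid.
#'
#' @param roi A `nanosep_roi`.
#' @return Tibble with `x_nm`, `y_nm`.
#' @export
localize_centroid <- function(roi) {
  counts <- roi$counts
  w <- pmax(counts - mean(roi_perimeter(counts)), 0)
  if (sum(w) == 0) {
    nanosep_abort("No intensity above background; centroid undefined.",
                  "nanosep_unfittable_error")
  }
  g <- roi_grid(roi)
  tibble(
    x_nm = sum(w %*% g$xc) / sum(w),
    y_nm = sum(t(w) %*% g$yc) / sum(w)
  )
}

#' Maximum-likelihood 2D Gaussian fit of a spot
#'
#' Maximizes the Poisson log-likelihood of the photon counts (counts
#' divided by camera gain) under the same pixel-integrated
#' Gaussian-plus-background model as [fit_gaussian_lsq()]. The most
#' accurate of the three estimators at low photon counts, at the cost of
#' computation. Convergence is relative change of the negative
#' log-likelihood; because the log-likelihood is much larger in magnitude
#' than its curvature near the optimum, the default tolerance is tighter
#' than the least-squares default.
#'
#' @inheritParams fit_gaussian_lsq
#' @param gain Counts per photon; default from the ROI metadata.
#' @param tol Relative tolerance on the negative log-likelihood
#'   (default `1e-8`).
#' @return A `spot_fit` with `method = "mle"`.
#' @export
fit_gaussian_mle <- function(roi, init = NULL, gain = NULL, tol = 1e-8,
                             max_iterations = 500) {
  if (is.null(gain)) gain <- roi$gain %||% 1
  if (gain <= 0) nanosep_abort("`gain` must be > 0.", "nanosep_domain_error")
  if (is.null(init)) init <- initial_estimate(roi)
  grid <- roi_grid(roi)
  photons <- as.vector(roi$counts) / gain
  theta0 <- c(max(init$z0, 1e-3) / gain, init$A / gain, init$x0, init$y0,
              init$sx, init$sy)
  nll <- function(theta) {
    mu <- pmax(as.vector(gauss_model_integrated(theta, grid)$m), 1e-10)
    sum(mu - photons * log(mu))
  }
  gr <- function(theta) {
    mj <- gauss_model_integrated(theta, grid, jacobian = TRUE)
    mu <- pmax(as.vector(mj$m), 1e-10)
    as.vector(crossprod(mj$J, 1 - photons / mu))
  }
  xr <- range(grid$xe); yr <- range(grid$ye)
  opt <- optim(theta0, nll, gr, method = "L-BFGS-B",
               lower = c(0, 1e-9, xr[1], yr[1], 2, 2),
               upper = c(Inf, Inf, xr[2], yr[2],
                         10 * init$sx, 10 * init$sy),
               control = list(maxit = max_iterations,
                              factr = tol / .Machine$double.eps))
  theta <- opt$par
  theta[1] <- theta[1] * gain  # back to counts
  theta[2] <- theta[2] * gain
  drifted <- theta[3] <= xr[1] || theta[3] >= xr[2] ||
    theta[4] <= yr[1] || theta[4] >= yr[2]
  fit <- new_spot_fit(roi, theta, rotated = FALSE, method = "mle",
                      n_iterations = opt$counts[["function"]],
                      converged = opt$convergence == 0 && !drifted,
                      drifted = drifted, residual_ss = NA_real_)
  fit$nll <- opt$value
  fit$nll_init <- nll(theta0)
  fit
}

#' Photon count of a fitted spot
#'
#' `N` is estimated as the total signal intensity before gain: summed
#' counts minus the fitted background, divided by the camera gain, clipped
#' at zero. The model-based alternative `2 pi A sx sy / (a^2 gain)` (the
#' analytic volume of the fitted Gaussian) is reported alongside as a
#' cross-check; the two agree when the fit is good and the spot sits well
#' inside the ROI.
#'
#' @param roi A `nanosep_roi`.
#' @param fit A `spot_fit` (supplies the fitted background `z0` and widths).
#' @param gain Counts per photon (> 0); default from ROI metadata.
#' @return List with `N_photons` (total-intensity estimate) and `N_model`.
#' @export
photons_from_counts <- function(roi, fit, gain = NULL) {
  if (is.null(gain)) gain <- roi$gain %||% 1
  if (gain <= 0) nanosep_abort("`gain` must be > 0.", "nanosep_domain_error")
  n_px <- length(roi$counts)
  N <- max((sum(roi$counts) - fit$z0 * n_px) / gain, 0)
  N_model <- 2 * pi * fit$A * fit$sx_nm * fit$sy_nm /
    (roi$pixel_size_nm^2 * gain)
  list(N_photons = N, N_model = N_model)
}

#' Localization precision of a fitted spot
#'
#' The statistical uncertainty (per axis) of a fitted spot center:
#' \deqn{\sigma = \sqrt{ s^2/N + a^2/(12N) + 8\pi s^4 b^2 / (a^2 N^2) }}
#' where `s` is the Gaussian spot width (for asymmetric fits, the geometric
#' mean `sqrt(sx sy)`), `N` the number of photons contributing to the spot,
#' `a` the pixel size and `b` the background noise in photons/pixel. The
#' three terms are photon shot noise, pixelation, and background.
#'
#' @param s_nm Spot width in nm (> 0).
#' @param photons Photon count `N` (> 0).
#' @param pixel_size_nm Pixel size `a` in nm (> 0).
#' @param background_noise_photons Background noise `b`, photons/pixel
#'   (>= 0). In this package `b` is estimated as the standard deviation of
#'   the perimeter-pixel photon values.
#' @return Precision in nm.
#' @examples
#' localization_precision(100, 1000, 200, 0)   # 3.65 nm
#' localization_precision(100, 1000, 200, 10)  # 4.43 nm
#' @export
localization_precision <- function(s_nm, photons, pixel_size_nm,
                                   background_noise_photons = 0) {
  if (any(s_nm <= 0) || any(pixel_size_nm <= 0) ||
      any(background_noise_photons < 0)) {
    nanosep_abort("`s_nm`, `pixel_size_nm` must be > 0 and `b` >= 0.",
                  "nanosep_domain_error")
  }
  if (any(photons <= 0)) {
    nanosep_abort("Localization precision is undefined for N <= 0.",
                  "nanosep_domain_error")
  }
  sqrt(s_nm^2 / photons + pixel_size_nm^2 / (12 * photons) +
         8 * pi * s_nm^4 * background_noise_photons^2 /
           (pixel_size_nm^2 * photons^2))
}

#' Localize all candidate foci in an image
#'
#' Pipeline surface for one channel: extract an ROI around each candidate,
#' initialize, and localize with the chosen estimator. Foci whose ROI
#' crosses the image edge, that are un-fittable, or whose fit does not
#' converge are excluded and counted in the `excluded` attribute.
#'
#' @param image A [nanosep_image()].
#' @param candidates Tibble with 0-based `x_px`, `y_px` candidate centers;
#'   default [find_candidate_foci()]. User-supplied click coordinates can
#'   be passed here directly.
#' @param method `"lsq"` (default), `"centroid"` or `"mle"`.
#' @param half_width_px ROI half-width (default from metadata).
#' @param keep_unconverged Keep non-converged fits (flagged) instead of
#'   dropping them? Default `FALSE`.
#' @param ... Passed to the fitting function.
#' @return Localization tibble: one row per localized focus with
#'   `x_px`, `y_px` (ROI anchor), `method`, `x_nm`, `y_nm`, `sx_nm`,
#'   `sy_nm`, `A`, `z0`, `N_photons`, `b_photons`, `sigma_nm`,
#'   `n_iterations`, `converged`.
#' @export
localize_spots <- function(image, candidates = NULL,
                           method = c("lsq", "centroid", "mle"),
                           half_width_px = NULL, keep_unconverged = FALSE,
                           ...) {
  method <- match.arg(method)
  if (is.null(candidates)) candidates <- find_candidate_foci(image)
  rows <- vector("list", nrow(candidates))
  excluded <- 0L
  for (i in seq_len(nrow(candidates))) {
    row <- tryCatch({
      roi <- extract_roi(image, c(candidates$x_px[i], candidates$y_px[i]),
                         half_width_px)
      localize_one(roi, method, ...)
    }, nanosep_error = function(e) NULL)
    if (is.null(row) || (!row$converged && !keep_unconverged)) {
      excluded <- excluded + 1L
      next
    }
    rows[[i]] <- row
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(x_px = integer(0), y_px = integer(0), method = character(0),
                  x_nm = numeric(0), y_nm = numeric(0), sx_nm = numeric(0),
                  sy_nm = numeric(0), A = numeric(0), z0 = numeric(0),
                  N_photons = numeric(0), b_photons = numeric(0),
                  sigma_nm = numeric(0), n_iterations = integer(0),
                  converged = logical(0))
  }
  attr(out, "excluded") <- excluded
  out
}

localize_one <- function(roi, method, ...) {
  if (method == "centroid") {
    cen <- localize_centroid(roi)
    z0 <- mean(roi_perimeter(roi$counts))
    gain <- roi$gain %||% 1
    N <- max((sum(roi$counts) - z0 * length(roi$counts)) / gain, 0)
    b <- sd(roi_perimeter(roi$counts)) / gain
    s <- roi_spot_width(roi)
    sigma <- if (N > 0) {
      localization_precision(s, N, roi$pixel_size_nm, b)
    } else NA_real_
    return(tibble(
      x_px = roi$anchor_px[["x"]], y_px = roi$anchor_px[["y"]],
      method = "centroid", x_nm = cen$x_nm, y_nm = cen$y_nm,
      sx_nm = NA_real_, sy_nm = NA_real_, A = NA_real_, z0 = z0,
      N_photons = N, b_photons = b, sigma_nm = sigma,
      n_iterations = 0L, converged = TRUE))
  }
  fit <- if (method == "lsq") fit_gaussian_lsq(roi, ...)
         else fit_gaussian_mle(roi, ...)
  tidy_fit_row(fit)
}

tidy_fit_row <- function(fit) {
  tibble(
    x_px = fit$anchor_px[["x"]], y_px = fit$anchor_px[["y"]],
    method = fit$method, x_nm = fit$x0_nm, y_nm = fit$y0_nm,
    sx_nm = fit$sx_nm, sy_nm = fit$sy_nm, A = fit$A, z0 = fit$z0,
    N_photons = fit$photons_N, b_photons = fit$b_photons,
    sigma_nm = fit$sigma_nm, n_iterations = fit$n_iterations,
    converged = fit$converged)
}

#' @export
tidy.spot_fit <- function(x, ...) tidy_fit_row(x)

#' @export
glance.spot_fit <- function(x, ...) {
  tibble(method = x$method, n_iterations = x$n_iterations,
         converged = x$converged, residual_ss = x$residual_ss,
         photons_N = x$photons_N, sigma_nm = x$sigma_nm)
}
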
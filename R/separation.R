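#' Pair two-color foci
#'
#' Mutual-nearest-neighbor pairing of channel-A and channel-B foci already
#' registered into the common (channel-A) frame, gated at the diffraction
#' limit: only pairs closer than `gate_nm` (default 200 nm) are accepted,
#' since two foci from the same allele appear as one diffraction-limited
#' colocalizing spot. Unpaired foci are reported in the `unpaired_a` /
#' `unpaired_b` attributes.
#'
#' @param foci_a,foci_b Localization tibbles with `x_nm`, `y_nm` (and
#'   ideally `sigma_nm`); all fits should be converged and channel B
#'   registered into the A frame.
#' @param gate_nm Pairing gate in nm (default 200, the diffraction limit).
#' @return Tibble of pairs: `x_a`, `y_a`, `sigma_a`, `x_b`, `y_b`,
#'   `sigma_b`, `pair_dist_nm`. May be empty.
#' @export
pair_foci <- function(foci_a, foci_b, gate_nm = 200) {
  fa <- as_tibble(foci_a); fb <- as_tibble(foci_b)
  empty <- tibble(x_a = numeric(0), y_a = numeric(0), sigma_a = numeric(0),
                  x_b = numeric(0), y_b = numeric(0), sigma_b = numeric(0),
                  pair_dist_nm = numeric(0))
  if (nrow(fa) == 0 || nrow(fb) == 0) {
    attr(empty, "unpaired_a") <- fa; attr(empty, "unpaired_b") <- fb
    return(empty)
  }
  D <- sqrt(outer(fa$x_nm, fb$x_nm, "-")^2 + outer(fa$y_nm, fb$y_nm, "-")^2)
  nn_ab <- apply(D, 1, which.min)
  nn_ba <- apply(D, 2, which.min)
  ia <- which(nn_ba[nn_ab] == seq_len(nrow(fa)))
  ib <- nn_ab[ia]
  keep <- D[cbind(ia, ib)] < gate_nm
  ia <- ia[keep]; ib <- ib[keep]
  out <- tibble(
    x_a = fa$x_nm[ia], y_a = fa$y_nm[ia],
    sigma_a = (fa[["sigma_nm"]] %||% rep(NA_real_, nrow(fa)))[ia],
    x_b = fb$x_nm[ib], y_b = fb$y_nm[ib],
    sigma_b = (fb[["sigma_nm"]] %||% rep(NA_real_, nrow(fb)))[ib],
    pair_dist_nm = D[cbind(ia, ib)]
  )
  attr(out, "unpaired_a") <- fa[setdiff(seq_len(nrow(fa)), ia), ]
  attr(out, "unpaired_b") <- fb[setdiff(seq_len(nrow(fb)), ib), ]
  out
}

#' Separations with propagated uncertainty
#'
#' For each registered two-color pair: the Euclidean separation `d` in the
#' common frame, the combined uncertainty (root-sum-square of the two
#' localization precisions and the residual channel misalignment `r`), and
#' the significance flag. A measured distance is meaningful only when it
#' exceeds `sqrt(sigma_A^2 + sigma_B^2 + r^2)` — uncertainty is mandatory,
#' so missing precisions or `r` are an error.
#'
#' @param pairs Pair tibble from [pair_foci()] (columns `x_a`, `y_a`,
#'   `sigma_a`, `x_b`, `y_b`, `sigma_b`; channel B already registered).
#' @param r_nm Residual channel misalignment in nm (from
#'   [residual_error()]).
#' @param sigma_a,sigma_b Optional scalar overrides for the per-channel
#'   precisions (used when the table carries none).
#' @return Tibble of separation records: inputs plus `d_nm`,
#'   `combined_uncertainty_nm`, `significant`.
#' @examples
#' p <- tibble::tibble(x_a = 0, y_a = 0, sigma_a = 15,
#'                     x_b = 30, y_b = 40, sigma_b = 15)
#' separations(p, r_nm = 21)  # d = 50, uncertainty ~30
#' @export
separations <- function(pairs, r_nm, sigma_a = NULL, sigma_b = NULL) {
  p <- as_tibble(pairs)
  if (missing(r_nm) || is.null(r_nm) || is.na(r_nm)) {
    nanosep_abort("Residual misalignment `r_nm` is mandatory.",
                  "nanosep_domain_error")
  }
  if (!is.null(sigma_a)) p$sigma_a <- sigma_a
  if (!is.null(sigma_b)) p$sigma_b <- sigma_b
  if (is.null(p[["sigma_a"]]) || is.null(p[["sigma_b"]]) ||
      any(is.na(p[["sigma_a"]])) || any(is.na(p[["sigma_b"]]))) {
    nanosep_abort("Per-channel precisions sigma_a/sigma_b are mandatory.",
                  "nanosep_domain_error")
  }
  p$d_nm <- sqrt((p$x_a - p$x_b)^2 + (p$y_a - p$y_b)^2)
  p$combined_uncertainty_nm <- sqrt(p$sigma_a^2 + p$sigma_b^2 + r_nm^2)
  p$r_nm <- r_nm
  p$significant <- p$d_nm > p$combined_uncertainty_nm
  p
}

#' Histogram of separations
#'
#' Bins separation magnitudes into half-open bins `[k w, (k+1) w)` of width
#' `w` (default 30 nm). Counts conserve the number of records.
#'
#' @param records Separation tibble (with `d_nm`) or a numeric vector of
#'   separations in nm.
#' @param bin_width_nm Bin width (default 30).
#' @return A `separation_distribution`: bin edges, centers, counts, `n`,
#'   and (after [fit_histogram_gaussian()]) the fitted Gaussian summary.
#' @export
histogram_separations <- function(records, bin_width_nm = 30) {
  d <- if (is.numeric(records)) records else as_tibble(records)$d_nm
  if (length(d) == 0) {
    nanosep_abort("No separations to histogram.", "nanosep_domain_error")
  }
  w <- bin_width_nm
  breaks <- seq(0, (floor(max(d) / w) + 1) * w, by = w)
  counts <- as.integer(table(cut(d, breaks, right = FALSE,
                                 include.lowest = FALSE)))
  structure(
    list(bin_width_nm = w, breaks = breaks,
         mids = breaks[-length(breaks)] + w / 2,
         counts = counts, n = length(d), separations = d, fit = NULL),
    class = "separation_distribution")
}

#' Gaussian fit to a separation histogram, with equal-area normalization
#'
#' Fits `amp * exp(-(x - mean)^2 / (2 sd^2))` to the bin centers and counts
#' by least squares, then rescales the amplitude so the analytic area
#' `amp * sd * sqrt(2 pi)` equals a shared reference area — distributions
#' normalized to the same reference can be overlaid and compared directly.
#' The circle marker customarily drawn on such histograms is the fitted
#' mean. With fewer than 3 nonzero bins the fit is degenerate and the
#' empirical mean is reported instead (flagged).
#'
#' @param dist A `separation_distribution`.
#' @param reference_area Shared reference area for normalization; default
#'   the distribution's own fitted area (normalized amplitude = raw
#'   amplitude).
#' @return The distribution with a `fit` list: `mean`, `sd`, `amplitude`,
#'   `area`, `amplitude_normalized`, `degenerate`.
#' @export
fit_histogram_gaussian <- function(dist, reference_area = NULL) {
  stopifnot(inherits(dist, "separation_distribution"))
  nz <- dist$counts > 0
  if (sum(nz) < 3) {
    dist$fit <- list(mean = mean(dist$separations), sd = sd(dist$separations),
                     amplitude = NA_real_, area = NA_real_,
                     amplitude_normalized = NA_real_, degenerate = TRUE)
    return(dist)
  }
  df <- data.frame(x = dist$mids, y = dist$counts)
  mu0 <- weighted.mean(df$x, df$y)
  sd0 <- max(sqrt(weighted.mean((df$x - mu0)^2, df$y)), dist$bin_width_nm / 2)
  fit <- tryCatch(
    nlsLM(y ~ amp * exp(-(x - mean)^2 / (2 * sd^2)), data = df,
          start = list(amp = max(df$y), mean = mu0, sd = sd0),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    dist$fit <- list(mean = mean(dist$separations), sd = sd(dist$separations),
                     amplitude = NA_real_, area = NA_real_,
                     amplitude_normalized = NA_real_, degenerate = TRUE)
    return(dist)
  }
  cf <- coef(fit)
  area <- cf[["amp"]] * abs(cf[["sd"]]) * sqrt(2 * pi)
  ref <- reference_area %||% area
  dist$fit <- list(mean = cf[["mean"]], sd = abs(cf[["sd"]]),
                   amplitude = cf[["amp"]], area = area,
                   amplitude_normalized = cf[["amp"]] * ref / area,
                   degenerate = FALSE)
  dist
}

#' Normalize several distributions to equal areas
#'
#' Rescales each fitted Gaussian amplitude so all analytic areas equal the
#' same reference (default 1), preserving relative bin proportions within
#' each distribution.
#'
#' @param dists List of fitted `separation_distribution`s.
#' @param reference_area Common area (default 1).
#' @return The list, with updated `amplitude_normalized` slots.
#' @export
normalize_distributions <- function(dists, reference_area = 1) {
  lapply(dists, function(d) {
    if (is.null(d$fit)) d <- fit_histogram_gaussian(d)
    if (!isTRUE(d$fit$degenerate)) {
      d$fit$amplitude_normalized <- d$fit$amplitude * reference_area / d$fit$area
    }
    d
  })
}

#' @export
print.separation_distribution <- function(x, ...) {
  cat(sprintf("<separation_distribution> n = %d, %g-nm bins, %d bins\n",
              x$n, x$bin_width_nm, length(x$counts)))
  if (!is.null(x$fit)) {
    cat(sprintf("  fitted mean %.1f nm, sd %.1f nm%s\n", x$fit$mean, x$fit$sd,
                if (isTRUE(x$fit$degenerate)) " (degenerate: empirical)" else ""))
  }
  invisible(x)
}

#' @export
tidy.separation_distribution <- function(x, ...) {
  tibble(bin_start_nm = x$breaks[-length(x$breaks)],
         bin_end_nm = x$breaks[-1], bin_mid_nm = x$mids, count = x$counts)
}

#' @export
glance.separation_distribution <- function(x, ...) {
  f <- x$fit %||% list(mean = NA_real_, sd = NA_real_, amplitude = NA_real_,
                       area = NA_real_, degenerate = NA)
  tibble(n = x$n, bin_width_nm = x$bin_width_nm,
         mean_nm = f$mean, sd_nm = f$sd, amplitude = f$amplitude,
         area = f$area, degenerate = isTRUE(f$degenerate))
}

#' Plot a separation histogram with its fitted Gaussian
#'
#' Bars are the binned occurrences; the curve is the fitted (normalized)
#' Gaussian and the circle marks its mean.
#'
#' @param object A `separation_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.separation_distribution <- function(object, ...) {
  bins <- tidy(object)
  p <- ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin_mid_nm, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_width_nm * 0.92,
                      fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "Separation (nm)", y = "Occurrence")
  f <- object$fit
  if (!is.null(f) && !isTRUE(f$degenerate)) {
    xs <- seq(0, max(object$breaks), length.out = 200)
    curve <- tibble(x = xs,
                    y = f$amplitude * exp(-(xs - f$mean)^2 / (2 * f$sd^2)))
    p <- p +
      ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$x, y = .data$y),
                         colour = "firebrick", linewidth = 0.8) +
      ggplot2::geom_point(data = tibble(x = f$mean, y = f$amplitude),
                          ggplot2::aes(x = .data$x, y = .data$y),
                          shape = 21, size = 3, fill = "white",
                          colour = "firebrick")
  }
  p
}

#' Probability of chance colocalization
#'
#' How often would a channel-A focus overlap an unrelated channel-B focus
#' if both were scattered at random over the nuclear area? Two foci
#' overlap when their centers fall within the sum of their radii, so the
#' overlap disc has area `pi (2 rho)^2 = 4 * spot_area` for equal spots.
#' The reported probability is
#' `1 - (1 - n_A * overlap_area / nuclear_area)^n_B`; for small expected
#' counts this is indistinguishable from the Poisson form
#' `1 - exp(-n_A n_B overlap_area / nuclear_area)`, which is also returned.
#'
#' @param spot_area_nm2 Area of one diffraction-limited focus (nm^2).
#' @param nuclear_area_nm2 Visible nuclear area (nm^2); must be much
#'   larger than the spot.
#' @param n_a,n_b Focus counts per nucleus in each channel.
#' @return Tibble with `p_overlap` and `p_overlap_poisson`.
#' @examples
#' # 200-nm spots in a 10 x 10 um nucleus, two foci per channel
#' chance_colocalization(pi * 100^2, 1e8, 2, 2)  # < 1 in a hundred
#' @export
chance_colocalization <- function(spot_area_nm2, nuclear_area_nm2, n_a, n_b) {
  if (spot_area_nm2 >= nuclear_area_nm2) {
    nanosep_abort("Spot area must be much smaller than the nuclear area.",
                  "nanosep_domain_error")
  }
  if (n_a < 0 || n_b < 0) {
    nanosep_abort("Focus counts must be non-negative.", "nanosep_domain_error")
  }
  overlap <- 4 * spot_area_nm2   # disc of radius = sum of the two spot radii
  frac <- min(n_a * overlap / nuclear_area_nm2, 1)
  tibble(
    p_overlap = 1 - (1 - frac)^n_b,
    p_overlap_poisson = 1 - exp(-n_a * n_b * overlap / nuclear_area_nm2)
  )
}
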
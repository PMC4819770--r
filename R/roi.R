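#' Extract a square region of interest around a focus
#'
#' Isolates a spot from the rest of the image as a square pixel block that
#' includes the spot "and a few pixels beyond" in each direction. The
#' default half-width is `ceiling(3 s / a) + 2` pixels, derived from the
#' channel's theoretical spot width.
#'
#' @param image A [nanosep_image()].
#' @param center_px Length-2 vector `(x_px, y_px)` of 0-based pixel indices.
#' @param half_width_px ROI half-width in pixels; the ROI side is
#'   `2 * half_width_px + 1`. Default derived from image metadata.
#' @return A `nanosep_roi`: the pixel block plus its anchor (0-based
#'   top-left pixel index in the parent image) and the parent metadata.
#' @examples
#' fr <- frame_geometry(64, 64, 200)
#' op <- optics_model(650, 1.45)
#' img <- render_spot(list(x_nm = 6500, y_nm = 6500, photons = 5000), fr, op)
#' roi <- extract_roi(img, c(32, 32), 4)
#' dim(roi$counts)  # 9 x 9
#' @export
extract_roi <- function(image, center_px, half_width_px = NULL) {
  stopifnot(inherits(image, "nanosep_image"), length(center_px) == 2)
  if (is.null(half_width_px)) {
    half_width_px <- default_half_width(image_spot_width(image),
                                        attr(image, "pixel_size_nm"))
  }
  half_width_px <- as.integer(half_width_px)
  if (half_width_px < 2) {
    nanosep_abort("ROI side must be >= 5 px.", "nanosep_domain_error")
  }
  cx <- as.integer(round(center_px[1])); cy <- as.integer(round(center_px[2]))
  x0 <- cx - half_width_px; x1 <- cx + half_width_px
  y0 <- cy - half_width_px; y1 <- cy + half_width_px
  if (x0 < 0 || y0 < 0 || x1 >= ncol(image) || y1 >= nrow(image)) {
    nanosep_abort(
      sprintf("ROI around (%d, %d) crosses the image edge.", cx, cy),
      "nanosep_edge_error")
  }
  m <- image_meta(image)
  structure(
    list(counts = unclass(image)[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)],
         anchor_px = c(x = x0, y = y0),
         pixel_size_nm = m$pixel_size_nm,
         wavelength_nm = m$wavelength_nm,
         numerical_aperture = m$numerical_aperture,
         gain = m$gain, channel = m$channel),
    class = "nanosep_roi")
}

#' @export
print.nanosep_roi <- function(x, ...) {
  cat(sprintf("<nanosep_roi> %d x %d px at anchor (%d, %d), channel %s\n",
              ncol(x$counts), nrow(x$counts), x$anchor_px[["x"]],
              x$anchor_px[["y"]], x$channel))
  invisible(x)
}

roi_perimeter <- function(counts) {
  n <- nrow(counts); m <- ncol(counts)
  c(counts[1, ], counts[n, ], counts[2:(n - 1), 1], counts[2:(n - 1), m])
}

roi_spot_width <- function(roi) {
  if (is.na(roi$wavelength_nm) || is.na(roi$numerical_aperture)) {
    nanosep_abort("ROI metadata lacks wavelength/NA.", "nanosep_metadata_error")
  }
  theoretical_width(roi$wavelength_nm, roi$numerical_aperture)
}

# pixel-center coordinates (nm, parent frame) of an ROI
roi_grid <- function(roi) {
  a <- roi$pixel_size_nm
  list(
    a = a,
    xc = (roi$anchor_px[["x"]] + seq_len(ncol(roi$counts)) - 1 + 0.5) * a,
    yc = (roi$anchor_px[["y"]] + seq_len(nrow(roi$counts)) - 1 + 0.5) * a,
    xe = (roi$anchor_px[["x"]] + 0:ncol(roi$counts)) * a,
    ye = (roi$anchor_px[["y"]] + 0:nrow(roi$counts)) * a
  )
}

#' Quality-control gate for a candidate focus
#'
#' A focus is accepted for localization only if it looks like a
#' diffraction-limited spot: Gaussian-like shape, adequate signal-to-noise
#' ratio, and adequate local contrast. The three reported statistics are
#'
#' * `snr`: (max pixel - perimeter mean) / perimeter mean — the brightness
#'   ratio above background; foci should be at least 3x brighter than
#'   background, i.e. `snr >= 3` by default (a peak at 4x background has
#'   `snr = 3`).
#' * `gaussian_likeness`: Pearson correlation between the ROI and its
#'   best-fit 2D Gaussian model (in `[0, 1]`, negative values clipped).
#' * `local_contrast`: (max pixel - perimeter mean) / perimeter standard
#'   deviation. A spot rising from a perfectly flat, non-zero perimeter is
#'   infinitely contrasted; a completely flat ROI has undefined contrast
#'   and fails.
#'
#' @param roi A `nanosep_roi`.
#' @param snr_min,gaussian_min,contrast_min Acceptance thresholds
#'   (defaults 3, 0.7, 5).
#' @return One-row tibble: `snr`, `gaussian_likeness`, `local_contrast`,
#'   `passed`, `failure_reasons` (list column of character vectors).
#' @export
qc_focus <- function(roi, snr_min = 3, gaussian_min = 0.7, contrast_min = 5) {
  counts <- roi$counts
  perim <- roi_perimeter(counts)
  pm <- mean(perim); psd <- sd(perim)
  peak <- max(counts)
  reasons <- character(0)

  snr <- if (pm > 0) (peak - pm) / pm else if (peak > 0) Inf else NA_real_
  if (is.na(snr) || snr < snr_min) reasons <- c(reasons, "low_snr")

  contrast <- if (psd > 0) {
    (peak - pm) / psd
  } else if (peak > pm) Inf else NA_real_
  if (is.na(contrast)) {
    reasons <- c(reasons, "flat_roi")
  } else if (contrast < contrast_min) {
    reasons <- c(reasons, "low_contrast")
  }

  likeness <- tryCatch({
    fit <- fit_gaussian_lsq(roi, max_iterations = 50)
    pred <- predict_fit_matrix(fit, roi)
    if (sd(pred) == 0 || sd(counts) == 0) NA_real_
    else max(0, stats::cor(as.vector(counts), as.vector(pred)))
  }, error = function(e) NA_real_)
  if (is.na(likeness) || likeness < gaussian_min) {
    reasons <- c(reasons, "not_gaussian")
  }

  tibble(
    snr = snr, gaussian_likeness = likeness, local_contrast = contrast,
    passed = length(reasons) == 0, failure_reasons = list(reasons)
  )
}

#' Find candidate foci in an image
#'
#' Automates the manual spot-picking step: local intensity maxima above
#' `median + k * MAD`, non-maximum suppressed at a `2 s` spacing, each then
#' checked with [qc_focus()]. Candidates are returned brightest-first, so
#' ordering is deterministic.
#'
#' @param image A [nanosep_image()].
#' @param snr_min,gaussian_min,contrast_min QC thresholds, see [qc_focus()].
#' @param k_mad Threshold in robust standard deviations above the image
#'   median (default 5).
#' @param half_width_px ROI half-width; default from image metadata.
#' @return Tibble of accepted candidates: `x_px`, `y_px` (0-based peak
#'   pixel), `peak_counts`, and the QC statistics. May be empty.
#' @export
find_candidate_foci <- function(image, snr_min = 3, gaussian_min = 0.7,
                                contrast_min = 5, k_mad = 5,
                                half_width_px = NULL) {
  counts <- unclass(image)
  thr <- median(counts) + k_mad * mad(counts)
  H <- nrow(counts); W <- ncol(counts)
  # strict local maxima over the 8-neighborhood, interior pixels only
  inner <- counts[2:(H - 1), 2:(W - 1)]
  is_max <- inner > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- counts[(2 + dy):(H - 1 + dy), (2 + dx):(W - 1 + dx)]
    is_max <- is_max & (inner >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty_candidates())
  cand <- tibble(
    x_px = idx[, 2] + 1L - 1L,  # back to full-image 0-based indices
    y_px = idx[, 1] + 1L - 1L,
    peak_counts = counts[cbind(idx[, 1] + 1L, idx[, 2] + 1L)]
  )
  cand <- arrange(cand, desc(.data$peak_counts), .data$y_px, .data$x_px)

  s <- tryCatch(image_spot_width(image), error = function(e) NA_real_)
  min_sep <- if (is.na(s)) 2 else 2 * s / attr(image, "pixel_size_nm")
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d <- sqrt((cand$x_px[keep] - cand$x_px[i])^2 +
              (cand$y_px[keep] - cand$y_px[i])^2)
    keep[i] <- all(d >= min_sep)
  }
  cand <- cand[keep, ]

  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    roi <- tryCatch(
      extract_roi(image, c(cand$x_px[i], cand$y_px[i]), half_width_px),
      nanosep_edge_error = function(e) NULL)
    if (is.null(roi)) next
    qc <- qc_focus(roi, snr_min, gaussian_min, contrast_min)
    if (qc$passed) rows[[i]] <- dplyr::bind_cols(cand[i, ], qc)
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) empty_candidates() else out
}

empty_candidates <- function() {
  tibble(x_px = integer(0), y_px = integer(0), peak_counts = numeric(0),
         snr = numeric(0), gaussian_likeness = numeric(0),
         local_contrast = numeric(0), passed = logical(0),
         failure_reasons = list())
}
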
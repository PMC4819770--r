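#' Match fiducial beads between two channels
#'
#' Pairs channel-A and channel-B bead localizations by mutual nearest
#' neighbors after subtracting the median displacement (so a large bulk
#' translation does not defeat the pairing). Pairs farther apart than
#' `max_pair_dist_nm` (after median-displacement removal) are rejected.
#' Both input tables should come from converged localizations.
#'
#' @param positions_a,positions_b Tibbles with `x_nm`, `y_nm` (and
#'   optionally `sigma_nm`) columns.
#' @param max_pair_dist_nm Rejection radius in nm (default 500).
#' @param min_pairs Minimum surviving pairs (default 12, the minimum
#'   number of fiduciary points a registration model needs).
#' @return Tibble of fiducial pairs: `x_a`, `y_a`, `x_b`, `y_b`,
#'   `pair_dist_nm` and, when available, `sigma_a`, `sigma_b`.
#' @export
match_fiducials <- function(positions_a, positions_b, max_pair_dist_nm = 500,
                            min_pairs = 12) {
  pa <- as_tibble(positions_a); pb <- as_tibble(positions_b)
  if (nrow(pa) == 0 || nrow(pb) == 0) {
    nanosep_abort("Need localizations in both channels.",
                  "nanosep_insufficient_fiducials")
  }
  dx <- median(outer_min_displacement(pa$x_nm, pb$x_nm, pa$y_nm, pb$y_nm)$dx)
  dy <- median(outer_min_displacement(pa$x_nm, pb$x_nm, pa$y_nm, pb$y_nm)$dy)
  bx <- pb$x_nm - dx; by <- pb$y_nm - dy
  D <- sqrt(outer(pa$x_nm, bx, "-")^2 + outer(pa$y_nm, by, "-")^2)
  nn_ab <- apply(D, 1, which.min)
  nn_ba <- apply(D, 2, which.min)
  ia <- which(nn_ba[nn_ab] == seq_len(nrow(pa)))  # mutual
  ib <- nn_ab[ia]
  d <- D[cbind(ia, ib)]
  keep <- d <= max_pair_dist_nm
  ia <- ia[keep]; ib <- ib[keep]
  pairs <- tibble(
    x_a = pa$x_nm[ia], y_a = pa$y_nm[ia],
    x_b = pb$x_nm[ib], y_b = pb$y_nm[ib],
    pair_dist_nm = sqrt((pa$x_nm[ia] - pb$x_nm[ib])^2 +
                          (pa$y_nm[ia] - pb$y_nm[ib])^2)
  )
  if (!is.null(pa[["sigma_nm"]])) pairs$sigma_a <- pa[["sigma_nm"]][ia]
  if (!is.null(pb[["sigma_nm"]])) pairs$sigma_b <- pb[["sigma_nm"]][ib]
  if (nrow(pairs) < min_pairs) {
    nanosep_abort(sprintf(
      "Only %d fiducial pairs survived matching; >= %d required.",
      nrow(pairs), min_pairs), "nanosep_insufficient_fiducials")
  }
  pairs
}

# for each b, displacement to nearest a (robust bulk-shift estimate)
outer_min_displacement <- function(xa, xb, ya, yb) {
  D <- sqrt(outer(xb, xa, "-")^2 + outer(yb, ya, "-")^2)
  j <- apply(D, 1, which.min)
  list(dx = xb - xa[j], dy = yb - ya[j])
}

#' Build a local-weighted-mean channel registration
#'
#' Constructs the nonrigid correction that maps channel-B positions into
#' the channel-A frame from matched fiducial pairs. For every control point
#' a second-order polynomial map of the local displacement field (A minus
#' B) is fitted to its `k` nearest control pairs, weighted by a Gaussian
#' falloff scaled to the k-th neighbor distance; the correction at a query
#' point is the weighted mean of these local polynomial maps under a
#' compact cubic kernel that fades each map out at the edge of its own
#' neighborhood. Because fiducial localizations are noisy and the
#' displacement field is smooth and small, the non-constant polynomial
#' terms carry a mild ridge penalty (`ridge`, in units of the local fit's
#' normalized coordinates); this stabilizes the twelve-point local fits
#' without biasing translations at all and with sub-2-nm bias for smooth
#' warps of realistic amplitude. By default the field is evaluated on a
#' coarse grid (pitch `grid_pitch_px` pixels) and bilinearly interpolated
#' between nodes; `evaluation = "direct"` evaluates the weighted mean
#' exactly at every query, which is slower but useful for validation.
#'
#' @param pairs Fiducial pairs from [match_fiducials()] (columns `x_a`,
#'   `y_a`, `x_b`, `y_b`). At least `k` pairs, not collinear.
#' @param k Neighbors per local polynomial fit (default 12, the minimum
#'   number of fiduciary points).
#' @param grid_pitch_px Grid pitch for the bilinear evaluation, in pixels
#'   (default 8).
#' @param pixel_size_nm Pixel size used to convert the grid pitch to nm
#'   (default 200).
#' @param evaluation `"grid"` (default) or `"direct"`.
#' @param ridge Ridge penalty on the non-constant local displacement
#'   terms (default 1; 0 gives plain weighted least squares).
#' @return An `lwm_transform` with the control pairs, local fits, the
#'   evaluation grid, and a `residual_nm` slot (`NA` until
#'   [residual_error()] is measured).
#' @export
build_lwm_transform <- function(pairs, k = 12, grid_pitch_px = 8,
                                pixel_size_nm = 200,
                                evaluation = c("grid", "direct"),
                                ridge = 1) {
  evaluation <- match.arg(evaluation)
  pairs <- as_tibble(pairs)
  n <- nrow(pairs)
  if (n < k) {
    nanosep_abort(sprintf("Need >= %d fiducial pairs, got %d.", k, n),
                  "nanosep_insufficient_fiducials")
  }
  # degenerate geometry: local quadratic fits need 2D spread
  X <- cbind(1, pairs$x_b, pairs$y_b)
  if (qr(scale(X[, 2:3], scale = FALSE))$rank < 2) {
    nanosep_abort("Fiducials are collinear; registration is ill-conditioned.",
                  "nanosep_conditioning_error")
  }

  # stage 1: unpenalized global order-2 polynomial of the displacement
  # field — captures translation, rotation and smooth low-order aberration
  # with minimal variance. Stage 2 below refines what the global map
  # misses, locally.
  cx <- mean(pairs$x_b); cy <- mean(pairs$y_b)
  sc <- max(sd(pairs$x_b), sd(pairs$y_b), 1)
  Ag <- poly2_design((pairs$x_b - cx) / sc, (pairs$y_b - cy) / sc)
  qg <- qr(Ag)
  global_x <- qr.coef(qg, pairs$x_a - pairs$x_b)
  global_y <- qr.coef(qg, pairs$y_a - pairs$y_b)
  if (anyNA(global_x) || anyNA(global_y)) {
    nanosep_abort("Degenerate fiducial geometry in the global fit.",
                  "nanosep_conditioning_error")
  }
  res_x <- (pairs$x_a - pairs$x_b) - as.vector(Ag %*% global_x)
  res_y <- (pairs$y_a - pairs$y_b) - as.vector(Ag %*% global_y)

  # stage 2: one ridge-stabilized local quadratic of the residual
  # displacement per control point, over its k nearest control pairs
  Dc <- as.matrix(stats::dist(cbind(pairs$x_b, pairs$y_b)))
  fits <- vector("list", n)
  radii <- numeric(n)
  pen <- diag(c(0, rep(ridge, 5)))
  for (i in seq_len(n)) {
    nb <- order(Dc[i, ])[seq_len(k)]    # includes the point itself
    h <- Dc[i, nb[k]]
    radii[i] <- h
    w <- exp(-(Dc[i, nb] / h)^2)
    # local coordinates centered on the control point, scaled by the
    # neighborhood radius
    A <- poly2_design((pairs$x_b[nb] - pairs$x_b[i]) / h,
                      (pairs$y_b[nb] - pairs$y_b[i]) / h)
    Aw <- A * sqrt(w)
    M <- crossprod(Aw) + pen
    beta_x <- tryCatch(
      solve(M, crossprod(Aw, res_x[nb] * sqrt(w))),
      error = function(e) {
        nanosep_abort("Degenerate fiducial geometry in a local fit.",
                      "nanosep_conditioning_error")
      })
    beta_y <- solve(M, crossprod(Aw, res_y[nb] * sqrt(w)))
    fits[[i]] <- cbind(as.vector(beta_x), as.vector(beta_y))
  }

  model <- structure(
    list(pairs = pairs, k = as.integer(k), fits = fits, radii = radii,
         ridge = ridge, center = c(cx, cy), scale = sc,
         global_x = as.vector(global_x), global_y = as.vector(global_y),
         grid_pitch_px = grid_pitch_px, pixel_size_nm = pixel_size_nm,
         evaluation = evaluation, residual_nm = NA_real_,
         hull = pairs[chull(pairs$x_b, pairs$y_b), c("x_b", "y_b")]),
    class = "lwm_transform")

  if (evaluation == "grid") {
    pitch <- grid_pitch_px * pixel_size_nm
    pad <- pitch
    gx <- seq(min(pairs$x_b) - pad, max(pairs$x_b) + pad + pitch, by = pitch)
    gy <- seq(min(pairs$y_b) - pad, max(pairs$y_b) + pad + pitch, by = pitch)
    g <- expand.grid(x = gx, y = gy)
    corr <- lwm_evaluate(model, g$x, g$y)
    model$grid <- list(
      x = gx, y = gy,
      fx = matrix(corr[, 1], nrow = length(gy), byrow = TRUE),
      fy = matrix(corr[, 2], nrow = length(gy), byrow = TRUE))
  }
  model
}

poly2_design <- function(x, y) cbind(1, x, y, x^2, x * y, y^2)

# direct weighted-mean evaluation of the corrected (A-frame) position for
# query points given in the B frame; each local map contributes only
# inside its own neighborhood radius (compact cubic kernel)
lwm_evaluate <- function(model, x, y) {
  p <- model$pairs
  Ag <- poly2_design((x - model$center[1]) / model$scale,
                     (y - model$center[2]) / model$scale)
  gx <- as.vector(Ag %*% model$global_x)
  gy <- as.vector(Ag %*% model$global_y)
  out <- matrix(NA_real_, length(x), 2)
  for (q in seq_along(x)) {
    d <- sqrt((p$x_b - x[q])^2 + (p$y_b - y[q])^2)
    R <- d / model$radii
    w <- ifelse(R < 1, 1 - 3 * R^2 + 2 * R^3, 0)
    idx <- which(w > 0)
    if (length(idx) == 0) {
      idx <- which.min(d)               # nearest local map (extrapolation)
      w[idx] <- 1
    }
    rx <- ry <- numeric(length(idx))
    for (j in seq_along(idx)) {
      i <- idx[j]
      A <- poly2_design((x[q] - p$x_b[i]) / model$radii[i],
                        (y[q] - p$y_b[i]) / model$radii[i])
      rx[j] <- sum(A * model$fits[[i]][, 1])
      ry[j] <- sum(A * model$fits[[i]][, 2])
    }
    wi <- w[idx]
    out[q, ] <- c(x[q] + gx[q] + sum(wi * rx) / sum(wi),
                  y[q] + gy[q] + sum(wi * ry) / sum(wi))
  }
  out
}

bilinear_interp <- function(gx, gy, F, x, y) {
  ix <- findInterval(x, gx, all.inside = TRUE)
  iy <- findInterval(y, gy, all.inside = TRUE)
  x0 <- gx[ix]; x1 <- gx[ix + 1]
  y0 <- gy[iy]; y1 <- gy[iy + 1]
  tx <- (x - x0) / (x1 - x0)
  ty <- (y - y0) / (y1 - y0)
  F[cbind(iy, ix)] * (1 - tx) * (1 - ty) +
    F[cbind(iy, ix + 1)] * tx * (1 - ty) +
    F[cbind(iy + 1, ix)] * (1 - tx) * ty +
    F[cbind(iy + 1, ix + 1)] * tx * ty
}

#' Apply a registration model to positions
#'
#' Maps channel-B positions into the channel-A frame. Deterministic for a
#' given model. Queries outside the convex hull of the control fiducials
#' are extrapolations: they are still corrected, but flagged.
#'
#' @param model An `lwm_transform`.
#' @param positions Data frame with `x_nm`, `y_nm` (channel-B frame).
#' @return Tibble of corrected positions with an `extrapolated` flag
#'   (other columns preserved).
#' @export
apply_transform <- function(model, positions) {
  stopifnot(inherits(model, "lwm_transform"))
  out <- as_tibble(positions)
  if (nrow(out) == 0) {
    out$extrapolated <- logical(0)
    return(out)
  }
  if (model$evaluation == "grid") {
    x_new <- bilinear_interp(model$grid$x, model$grid$y, model$grid$fx,
                             out$x_nm, out$y_nm)
    y_new <- bilinear_interp(model$grid$x, model$grid$y, model$grid$fy,
                             out$x_nm, out$y_nm)
  } else {
    corr <- lwm_evaluate(model, out$x_nm, out$y_nm)
    x_new <- corr[, 1]; y_new <- corr[, 2]
  }
  hull <- model$hull
  inside <- mgcv::in.out(
    rbind(as.matrix(hull), as.matrix(hull[1, ])),
    cbind(out$x_nm, out$y_nm))
  if (any(!inside)) {
    warn(sprintf("%d position(s) outside the calibrated fiducial hull; extrapolated.",
                 sum(!inside)))
  }
  out$x_nm <- x_new
  out$y_nm <- y_new
  out$extrapolated <- !inside
  out
}

#' Residual misalignment on held-out beads
#'
#' Root-mean-square distance between corrected channel-B and channel-A
#' positions over a hold-out set of fiducial pairs that took no part in
#' building the model. This residual `r` must be propagated into the total
#' uncertainty of every separation measured with the model.
#'
#' @param model An `lwm_transform`.
#' @param heldout_pairs Fiducial pairs disjoint from the control pairs.
#' @return Residual misalignment `r` in nm.
#' @export
residual_error <- function(model, heldout_pairs) {
  hp <- as_tibble(heldout_pairs)
  if (nrow(hp) == 0) {
    nanosep_abort("Hold-out set is empty.", "nanosep_domain_error")
  }
  corrected <- suppressWarnings(
    apply_transform(model, tibble(x_nm = hp$x_b, y_nm = hp$y_b)))
  sqrt(mean((corrected$x_nm - hp$x_a)^2 + (corrected$y_nm - hp$y_a)^2))
}

#' @export
print.lwm_transform <- function(x, ...) {
  cat(sprintf(
    "<lwm_transform> %d control pairs, k = %d, %s evaluation, residual %s nm\n",
    nrow(x$pairs), x$k, x$evaluation,
    if (is.na(x$residual_nm)) "(unmeasured)" else sprintf("%.1f", x$residual_nm)))
  invisible(x)
}

#' @export
tidy.lwm_transform <- function(x, ...) {
  corrected <- suppressWarnings(
    apply_transform(x, tibble(x_nm = x$pairs$x_b, y_nm = x$pairs$y_b)))
  mutate(x$pairs,
         x_b_corrected = corrected$x_nm,
         y_b_corrected = corrected$y_nm,
         residual_nm = sqrt((corrected$x_nm - x$pairs$x_a)^2 +
                              (corrected$y_nm - x$pairs$y_a)^2))
}

#' @export
glance.lwm_transform <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs), k = x$k,
         grid_pitch_px = x$grid_pitch_px, evaluation = x$evaluation,
         residual_nm = x$residual_nm)
}

#' Serialize / restore a registration model
#'
#' The model is stored as a TSV of control pairs with a small metadata
#' header (`k`, grid pitch, pixel size, measured residual); on reading, the
#' transform is rebuilt deterministically from the pairs.
#'
#' @param model An `lwm_transform`.
#' @param path File path.
#' @return `write_registration_model()` returns `path` invisibly;
#'   `read_registration_model()` returns the restored `lwm_transform`.
#' @export
write_registration_model <- function(model, path) {
  header <- c(
    sprintf("# nanosep registration model"),
    sprintf("# k: %d", model$k),
    sprintf("# grid_pitch_px: %g", model$grid_pitch_px),
    sprintf("# pixel_size_nm: %g", model$pixel_size_nm),
    sprintf("# evaluation: %s", model$evaluation),
    sprintf("# ridge: %g", model$ridge),
    sprintf("# residual_nm: %g", model$residual_nm))
  writeLines(header, path)
  cols <- intersect(c("x_a", "y_a", "x_b", "y_b", "pair_dist_nm",
                      "sigma_a", "sigma_b"), names(model$pairs))
  suppressMessages(
    write_tsv(model$pairs[, cols], path, append = TRUE, col_names = TRUE))
  invisible(path)
}

#' @rdname write_registration_model
#' @export
read_registration_model <- function(path) {
  lines <- readLines(path, n = 12)
  get_meta <- function(key, cast = as.numeric) {
    ln <- grep(paste0("^# ", key, ": "), lines, value = TRUE)
    if (length(ln) == 0) return(NULL)
    cast(sub(paste0("^# ", key, ": "), "", ln[1]))
  }
  pairs <- suppressMessages(
    read_tsv(path, comment = "#", show_col_types = FALSE))
  model <- build_lwm_transform(
    pairs,
    k = get_meta("k", as.integer) %||% 12L,
    grid_pitch_px = get_meta("grid_pitch_px") %||% 8,
    pixel_size_nm = get_meta("pixel_size_nm") %||% 200,
    evaluation = get_meta("evaluation", as.character) %||% "grid",
    ridge = get_meta("ridge") %||% 1)
  model$residual_nm <- get_meta("residual_nm") %||% NA_real_
  model
}
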
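#' Smooth inter-channel spatial warp
#'
#' Residual chromatic aberration displaces the apparent position of a
#' channel-B emitter relative to channel A by a smooth, slowly varying
#' vector field. The warp model used here is translation + rotation about
#' the frame center + low-order (quadratic) polynomial terms in coordinates
#' normalized to the frame half-size:
#' \deqn{dx(x, y) = t_x + (\cos\theta - 1) x_c - \sin\theta\, y_c +
#'       q_{x1} u^2 + q_{x2} u v + q_{x3} v^2}
#' and symmetrically for `dy`, where `(x_c, y_c)` are coordinates relative
#' to the frame center and `(u, v)` are those coordinates divided by the
#' frame half-width/half-height.
#'
#' @param frame A [frame_geometry()] the warp is defined over.
#' @param translation_nm Length-2 translation `(tx, ty)` in nm.
#' @param rotation_rad Rotation about the frame center, radians.
#' @param quad_x,quad_y Length-3 quadratic coefficients (nm at the frame
#'   corner) for the `u^2`, `uv`, `v^2` terms of `dx` and `dy`.
#' @param max_displacement_nm Optional bound: constructor errors if the
#'   warp displaces any point of the frame farther than this.
#' @return A `channel_warp` object.
#' @examples
#' fr <- frame_geometry(64, 64, 200)
#' w <- channel_warp(fr, translation_nm = c(50, 0))
#' apply_warp(w, tibble::tibble(x_nm = 1000, y_nm = 1000))
#' @export
channel_warp <- function(frame, translation_nm = c(0, 0), rotation_rad = 0,
                         quad_x = c(0, 0, 0), quad_y = c(0, 0, 0),
                         max_displacement_nm = NULL) {
  stopifnot(inherits(frame, "frame_geometry"),
            length(translation_nm) == 2, length(quad_x) == 3,
            length(quad_y) == 3)
  w <- structure(
    list(frame = frame,
         translation_nm = as.numeric(translation_nm),
         rotation_rad = as.numeric(rotation_rad),
         quad_x = as.numeric(quad_x), quad_y = as.numeric(quad_y)),
    class = "channel_warp"
  )
  achieved <- warp_max_displacement(w)
  if (!is.null(max_displacement_nm) && achieved > max_displacement_nm + 1e-9) {
    nanosep_abort(sprintf(
      "Warp displaces up to %.1f nm, above the stated bound %.1f nm.",
      achieved, max_displacement_nm), "nanosep_domain_error")
  }
  # invertibility over the frame: displacements must stay well below the
  # frame size so the map cannot fold
  lim <- 0.25 * min(frame$width_px, frame$height_px) * frame$pixel_size_nm
  if (achieved > lim) {
    nanosep_abort("Warp displacement too large to remain invertible over the frame.",
                  "nanosep_domain_error")
  }
  w$max_displacement_nm <- achieved
  w
}

#' @rdname channel_warp
#' @export
warp_identity <- function(frame) channel_warp(frame)

#' @rdname channel_warp
#' @export
warp_translation <- function(frame, tx_nm, ty_nm = 0) {
  channel_warp(frame, translation_nm = c(tx_nm, ty_nm))
}

#' @rdname channel_warp
#' @param seed Integer seed for the random draw.
#' @details `warp_random()` draws a random translation + rotation + quadratic
#'   warp and rescales it so the maximum displacement over the frame equals
#'   `max_displacement_nm` — a convenient stand-in for a day's residual
#'   chromatic aberration.
#' @export
warp_random <- function(frame, max_displacement_nm = 30, seed = 1) {
  with_seed(as.integer(seed), {
    w <- channel_warp(
      frame,
      translation_nm = runif(2, -1, 1),
      rotation_rad = runif(1, -1, 1) * 1e-4,
      quad_x = runif(3, -1, 1), quad_y = runif(3, -1, 1)
    )
  })
  achieved <- warp_max_displacement(w)
  f <- max_displacement_nm / achieved
  channel_warp(frame,
               translation_nm = w$translation_nm * f,
               rotation_rad = w$rotation_rad * f,
               quad_x = w$quad_x * f, quad_y = w$quad_y * f)
}

warp_displacement <- function(warp, x_nm, y_nm) {
  fr <- warp$frame
  cx <- fr$width_px * fr$pixel_size_nm / 2
  cy <- fr$height_px * fr$pixel_size_nm / 2
  xc <- x_nm - cx; yc <- y_nm - cy
  u <- xc / cx; v <- yc / cy
  th <- warp$rotation_rad
  dx <- warp$translation_nm[1] + (cos(th) - 1) * xc - sin(th) * yc +
    warp$quad_x[1] * u^2 + warp$quad_x[2] * u * v + warp$quad_x[3] * v^2
  dy <- warp$translation_nm[2] + sin(th) * xc + (cos(th) - 1) * yc +
    warp$quad_y[1] * u^2 + warp$quad_y[2] * u * v + warp$quad_y[3] * v^2
  cbind(dx, dy)
}

warp_max_displacement <- function(warp) {
  fr <- warp$frame
  gx <- seq(0, fr$width_px * fr$pixel_size_nm, length.out = 17)
  gy <- seq(0, fr$height_px * fr$pixel_size_nm, length.out = 17)
  g <- expand.grid(x = gx, y = gy)
  d <- warp_displacement(warp, g$x, g$y)
  max(sqrt(d[, 1]^2 + d[, 2]^2))
}

#' Apply a channel warp to positions
#'
#' Maps true channel-B positions to their apparent (aberrated) positions.
#'
#' @param warp A [channel_warp()].
#' @param positions Data frame with `x_nm`, `y_nm` columns.
#' @return A tibble with displaced `x_nm`, `y_nm` (other columns preserved).
#' @export
apply_warp <- function(warp, positions) {
  stopifnot(inherits(warp, "channel_warp"))
  d <- warp_displacement(warp, positions$x_nm, positions$y_nm)
  out <- as_tibble(positions)
  out$x_nm <- positions$x_nm + d[, 1]
  out$y_nm <- positions$y_nm + d[, 2]
  out
}

#' @export
print.channel_warp <- function(x, ...) {
  cat(sprintf(
    "<channel_warp> translation (%.1f, %.1f) nm, rotation %.2g rad, max displacement %.1f nm\n",
    x$translation_nm[1], x$translation_nm[2], x$rotation_rad,
    x$max_displacement_nm %||% warp_max_displacement(x)))
  invisible(x)
}
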
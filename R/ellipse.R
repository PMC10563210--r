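#' Standard deviational ellipse (directional distribution)
#'
#' Summarises the central tendency, dispersion and orientation of a
#' (optionally weighted) point distribution: the weighted mean centre, the
#' rotation of the principal axis in degrees clockwise from north, and the
#' standard deviations along the rotated axes (level = 1 SD). The rotation
#' follows the standard GIS formula
#' \deqn{\tan\theta = \frac{(A - B) + \sqrt{(A-B)^2 + 4C^2}}{2C},}
#' with \eqn{A = \sum w x'^2}, \eqn{B = \sum w y'^2}, \eqn{C = \sum w x' y'}
#' over the weight-normalised centred coordinates. `sigma_x` is the SD along
#' the \eqn{\theta} axis (the variance-maximising direction), `sigma_y`
#' along its perpendicular.
#'
#' Degenerate inputs (collinear or coincident points) return an ellipse with
#' a zero axis and `degenerate = TRUE` plus a warning.
#'
#' @param points Two-column matrix or data frame of planar (x, y) points
#'   (at least 3).
#' @param weights Optional non-negative weights with positive total.
#' @return An `sde_ellipse` list: `center` (x, y), `theta` (degrees
#'   clockwise from north, in `[0, 180)`), `sigma_x`, `sigma_y`, `level`,
#'   `degenerate`.
#' @export
std_dev_ellipse <- function(points, weights = NULL) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 3L) stop_arg("need at least 3 points")
  if (any(!is.finite(pts))) stop_arg("points must be finite")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0) {
    stop_arg("weights must be non-negative with positive total")
  }
  w <- weights / sum(weights)
  cx <- sum(w * pts[, 1L]); cy <- sum(w * pts[, 2L])
  xd <- pts[, 1L] - cx; yd <- pts[, 2L] - cy
  A <- sum(w * xd^2); B <- sum(w * yd^2); C <- sum(w * xd * yd)

  if (abs(C) < 1e-300) {
    theta <- if (A >= B) 90 else 0  # spread along x = east, else north
  } else {
    t <- ((A - B) + sqrt((A - B)^2 + 4 * C^2)) / (2 * C)
    theta <- atan(t) * 180 / pi
    if (theta < 0) theta <- theta + 180
  }
  th <- theta * pi / 180
  # axis direction clockwise from north: (sin th, cos th)
  var1 <- A * sin(th)^2 + B * cos(th)^2 + 2 * C * sin(th) * cos(th)
  var2 <- A * cos(th)^2 + B * sin(th)^2 - 2 * C * sin(th) * cos(th)
  sigma_x <- sqrt(max(var1, 0))
  sigma_y <- sqrt(max(var2, 0))
  degenerate <- min(sigma_x, sigma_y) < 1e-12 * max(sigma_x, sigma_y, 1)
  if (degenerate) {
    warning("degenerate standard deviational ellipse (collinear or coincident points)",
            call. = FALSE)
  }
  structure(list(center = c(x = cx, y = cy), theta = theta,
                 sigma_x = sigma_x, sigma_y = sigma_y, level = 1,
                 degenerate = degenerate),
            class = "sde_ellipse")
}

#' @export
print.sde_ellipse <- function(x, ...) {
  cat("<sde_ellipse> center (", format(x$center[1L], digits = 4), ", ",
      format(x$center[2L], digits = 4), "), theta = ",
      format(x$theta, digits = 4), " deg (cw from north), axes ",
      format(x$sigma_x, digits = 4), " / ", format(x$sigma_y, digits = 4),
      if (x$degenerate) "  [degenerate]" else "", "\n", sep = "")
  invisible(x)
}

#' Polygon approximation of an SDE ellipse
#'
#' Returns a closed ring of `n_vertices` points tracing the ellipse at
#' `scale` standard deviations, suitable for writing to GeoJSON.
#'
#' @param ellipse An `sde_ellipse`.
#' @param n_vertices Number of distinct vertices (default 64).
#' @param scale SD multiplier (default 1).
#' @return A closed two-column matrix (first row repeated last).
#' @export
ellipse_polygon <- function(ellipse, n_vertices = 64L, scale = 1) {
  stopifnot(inherits(ellipse, "sde_ellipse"))
  th <- ellipse$theta * pi / 180
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)
  # ellipse frame: u along theta axis (sin th, cos th), v perpendicular
  u <- scale * ellipse$sigma_x * cos(ang)
  v <- scale * ellipse$sigma_y * sin(ang)
  x <- ellipse$center[1L] + u * sin(th) + v * cos(th)
  y <- ellipse$center[2L] + u * cos(th) - v * sin(th)
  cbind(x = x, y = y)
}
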
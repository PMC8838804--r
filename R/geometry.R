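# Contour geometry: control points -> dense curves, arc length, nearest
# distances, rigid rotation, and a small acoustic-resolution utility.
# A "curve" throughout the package is a numeric matrix with two columns
# (x, y), rows ordered along the curve. Units are whatever the caller put
# in (metrics assume mm).

.as_xy <- function(points) {
  if (inherits(points, "frame_keypoints")) {
    return(cbind(x = points$x, y = points$y))
  }
  m <- as.matrix(points)
  if (ncol(m) != 2L) stop("points must have two columns (x, y)")
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  m
}

#' Interpolate ordered control points into a dense cubic-spline curve
#'
#' Fits a natural cubic interpolating spline through the control points,
#' parameterized by cumulative chord length, and samples it at `n` equally
#' spaced parameter values. The curve passes through every control point;
#' its first and last samples equal the first and last control points. Two
#' control points give a straight segment.
#'
#' Contour metrics in this package resample both compared contours to the
#' same density (default 100 samples) before computing distances.
#'
#' @param control Ordered control points: a two-column matrix/data frame or
#'   a [frame_keypoints()] (rows in anatomical order).
#' @param n Number of output samples (>= 2; default 100).
#' @return An `n` x 2 curve matrix.
#' @export
interpolate_spline <- function(control, n = 100L) {
  pts <- .as_xy(control)
  if (nrow(pts) < 2L) stop("need at least 2 control points")
  if (any(!is.finite(pts))) stop("control points must be finite")
  if (!is.numeric(n) || n < 2L) stop("n must be at least 2")
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
    pts[-nrow(pts), , drop = FALSE])^2))
  if (any(seg == 0)) stop("coincident consecutive control points")
  tt <- c(0, cumsum(seg))
  tq <- seq(0, tt[length(tt)], length.out = n)
  x <- stats::spline(tt, pts[, 1L], method = "natural", xout = tq)$y
  y <- stats::spline(tt, pts[, 2L], method = "natural", xout = tq)$y
  cbind(x = x, y = y)
}

#' Arc length of a sampled curve
#'
#' Sum of Euclidean lengths of consecutive sample segments. A single point
#' has length 0.
#'
#' @param curve A curve matrix (rows ordered along the curve).
#' @return Length in the curve's units.
#' @export
arc_length <- function(curve) {
  m <- .as_xy(curve)
  if (nrow(m) < 2L) return(0)
  sum(sqrt(rowSums((m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)))
}

#' Nearest sample of a curve to a point
#'
#' Minimum Euclidean distance from `p` to the curve's samples, with ties
#' broken by the lowest sample index.
#'
#' @param p Length-2 numeric (x, y).
#' @param curve A curve matrix.
#' @return List with `distance` and `index` of the nearest sample.
#' @export
nearest_distance <- function(p, curve) {
  m <- .as_xy(curve)
  if (!nrow(m)) stop("curve must be non-empty")
  d2 <- (m[, 1L] - p[1L])^2 + (m[, 2L] - p[2L])^2
  i <- which.min(d2)
  list(distance = sqrt(d2[i]), index = i)
}

#' Rigidly rotate points about an origin
#'
#' @param points A two-column matrix (or length-2 vector) of points.
#' @param angle Rotation angle in radians (counter-clockwise in a y-up
#'   frame; the package applies it consistently in image coordinates too,
#'   where all derived metrics are distance-based).
#' @param origin Centre of rotation (default the coordinate origin).
#' @return Rotated points, same shape as the input.
#' @export
rotate_points <- function(points, angle, origin = c(0, 0)) {
  vec <- is.null(dim(points)) && length(points) == 2L
  m <- if (vec) matrix(points, 1L) else .as_xy(points)
  ca <- cos(angle)
  sa <- sin(angle)
  dx <- m[, 1L] - origin[1L]
  dy <- m[, 2L] - origin[2L]
  out <- cbind(
    x = origin[1L] + ca * dx - sa * dy,
    y = origin[2L] + sa * dx + ca * dy
  )
  if (vec) c(out) else out
}

#' Axial resolution of an ultrasonic pulse
#'
#' The axial (along-beam) resolution of a pulse of `n_cycles` cycles at
#' carrier frequency `freq` Hz travelling at `speed` m/s is half the pulse
#' length: `n_cycles * 0.5 * speed / freq`, returned in mm. For a 3-cycle
#' 3 MHz pulse in soft tissue (1540 m/s) this is 0.77 mm, which bounds the
#' precision obtainable from any contour drawn on such an image.
#'
#' @param n_cycles Number of cycles in the pulse (>= 1).
#' @param freq Carrier frequency in Hz.
#' @param speed Speed of sound in m/s (default 1540, soft tissue).
#' @return Resolution in mm.
#' @export
axial_resolution <- function(n_cycles, freq, speed = 1540) {
  if (!is.numeric(n_cycles) || any(n_cycles < 1)) stop("n_cycles must be >= 1")
  if (!is.numeric(freq) || any(freq <= 0)) stop("freq must be positive")
  if (!is.numeric(speed) || any(speed <= 0)) stop("speed must be positive")
  n_cycles * 0.5 * speed / freq * 1000
}
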
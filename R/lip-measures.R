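# Lip measurement suite. A lip frame carries the eight named keypoints
# labelled on a front-facing camera image: A and B are the commissures
# (mouth corners), C and D the centre of the upper and lower lip (philtrum
# midline, not necessarily equidistant from A and B), E/G the upper-lip
# points midway along the arcs A-C and B-C, and F/H the lower-lip points
# midway along A-D and B-D.

#' Construct a lip keypoint frame
#'
#' Convenience constructor for a [frame_keypoints()] holding the eight lip
#' keypoints A-H.
#'
#' @param points 8 x 2 numeric matrix with rownames A-H (any order), or a
#'   named list of length-2 points.
#' @param confidence Confidence per point (recycled).
#' @param frame_index,time_s As in [frame_keypoints()].
#' @return A `frame_keypoints` with names A-H.
#' @export
lip_frame <- function(points, confidence = 1, frame_index = 0L,
                      time_s = NA_real_) {
  if (is.list(points) && !is.data.frame(points)) {
    points <- do.call(rbind, points)
  }
  m <- as.matrix(points)
  if (is.null(rownames(m))) stop("lip points must be named A-H")
  miss <- setdiff(lip_keypoints, rownames(m))
  if (length(miss)) {
    stop("missing lip keypoints: ", paste(miss, collapse = ", "))
  }
  m <- m[lip_keypoints, , drop = FALSE]
  frame_keypoints(lip_keypoints, m[, 1L], m[, 2L], confidence,
    frame_index = frame_index, time_s = time_s
  )
}

.lip_point <- function(frame, nm) {
  i <- match(nm, frame$name)
  if (is.na(i) || !is.finite(frame$x[i]) || !is.finite(frame$y[i])) {
    stop("lip keypoint '", nm, "' is missing")
  }
  c(frame$x[i], frame$y[i])
}

.lip_points <- function(frame, nms) {
  do.call(rbind, lapply(nms, .lip_point, frame = frame))
}

#' Upper and lower lip splines
#'
#' Builds the two lip contours as cubic interpolating splines sharing the
#' commissures as endpoints: the upper lip through A, E, C, G, B and the
#' lower lip through A, F, D, H, B, each sampled to `n` points.
#'
#' @param frame A lip [frame_keypoints()] with points A-H.
#' @param n Samples per curve (default 100).
#' @return List with `upper` and `lower` curve matrices; both start at A
#'   and end at B.
#' @export
lip_splines <- function(frame, n = 100L) {
  upper <- interpolate_spline(.lip_points(frame, c("A", "E", "C", "G", "B")), n)
  lower <- interpolate_spline(.lip_points(frame, c("A", "F", "D", "H", "B")), n)
  list(upper = upper, lower = lower)
}

#' Lip width
#'
#' Euclidean distance between the commissure keypoints A and B.
#'
#' @param frame A lip [frame_keypoints()] (only A and B are required).
#' @return Width in the frame's units.
#' @export
lip_width <- function(frame) {
  a <- .lip_point(frame, "A")
  b <- .lip_point(frame, "B")
  sqrt(sum((a - b)^2))
}

# TRUE if polylines P and Q intersect anywhere other than shared endpoints.
.polylines_cross <- function(P, Q) {
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  n <- nrow(P) - 1L
  m <- nrow(Q) - 1L
  # skip the first and last segments of each (they share A and B)
  for (i in 2:(n - 1L)) {
    p1 <- P[i, ]; p2 <- P[i + 1L, ]
    d1 <- cross(p1[1], p1[2], p2[1], p2[2], Q[2:m, 1], Q[2:m, 2])
    d2 <- cross(p1[1], p1[2], p2[1], p2[2], Q[3:(m + 1L), 1], Q[3:(m + 1L), 2])
    cand <- which(d1 * d2 < 0)
    for (k in cand) {
      q1 <- Q[k + 1L, ]; q2 <- Q[k + 2L, ]
      e1 <- cross(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2])
      e2 <- cross(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])
      if (e1 * e2 < 0) return(TRUE)
    }
  }
  FALSE
}

#' Lip aperture area
#'
#' Area (in squared input units) enclosed between the upper and lower lip
#' splines, computed as the absolute shoelace area of the closed polygon
#' formed by the upper-lip samples followed by the reversed interior
#' lower-lip samples. A closed mouth (identical splines) has area 0. If the
#' two splines cross, the absolute net area is returned with a warning.
#'
#' @param frame A lip [frame_keypoints()] with all of A-H.
#' @param n Samples per lip spline (default 100).
#' @return Aperture area.
#' @export
lip_aperture <- function(frame, n = 100L) {
  sp <- lip_splines(frame, n)
  if (.polylines_cross(sp$upper, sp$lower)) {
    warning("upper and lower lip splines cross; reporting absolute net area")
  }
  lower_int <- sp$lower[rev(seq(2L, nrow(sp$lower) - 1L)), , drop = FALSE]
  poly <- rbind(sp$upper, lower_int)
  xs <- poly[, 1L]
  ys <- poly[, 2L]
  xn <- c(xs[-1L], xs[1L])
  yn <- c(ys[-1L], ys[1L])
  abs(sum(xs * yn - xn * ys)) / 2
}

#' Lip rounding index
#'
#' A dimensionless, width-normalized measure of lip rounding:
#' `(|C - D| - 0.5 (|E - F| + |G - H|)) / |A - B|`, where `|. - .|` is the
#' Euclidean distance between keypoints (set `distance = "vertical"` to use
#' only the vertical separation instead). Rounded lips raise the midline
#' separation C-D relative to the parasagittal separations and shrink the
#' width A-B, so the index grows; a neutral spread mouth scores near 0.
#'
#' @param frame A lip [frame_keypoints()] with all of A-H.
#' @param distance `"euclidean"` (default) or `"vertical"`.
#' @return The rounding index (unitless; invariant under uniform scaling).
#' @export
lip_rounding <- function(frame, distance = c("euclidean", "vertical")) {
  distance <- match.arg(distance)
  dd <- function(p, q) {
    if (distance == "euclidean") sqrt(sum((p - q)^2)) else abs(p[2L] - q[2L])
  }
  A <- .lip_point(frame, "A"); B <- .lip_point(frame, "B")
  C <- .lip_point(frame, "C"); D <- .lip_point(frame, "D")
  E <- .lip_point(frame, "E"); F <- .lip_point(frame, "F")
  G <- .lip_point(frame, "G"); H <- .lip_point(frame, "H")
  w <- sqrt(sum((A - B)^2))
  if (w == 0) stop("commissures coincide: zero lip width")
  (dd(C, D) - 0.5 * (dd(E, F) + dd(G, H))) / w
}

#' Compare estimated lip keypoints against hand labels
#'
#' Per-lip modified MSD between the hand and estimated lip splines, plus
#' signed width and aperture differences. Differences use the convention
#' estimate minus hand label, so an estimator that marks a smaller mouth
#' area than the labeller yields a negative aperture difference.
#'
#' @param hand,est Complete lip [frame_keypoints()].
#' @param n Samples per lip spline (default 100).
#' @return List of class `lip_eval_frame` with `msd_upper_mm`,
#'   `msd_lower_mm`, `width_diff`, `aperture_diff`, `rounding_hand`,
#'   `rounding_est`.
#' @export
evaluate_lips <- function(hand, est, n = 100L) {
  sph <- lip_splines(hand, n)
  spe <- lip_splines(est, n)
  structure(
    list(
      msd_upper_mm = msd_modified(sph$upper, spe$upper)$msd_mm,
      msd_lower_mm = msd_modified(sph$lower, spe$lower)$msd_mm,
      width_diff = lip_width(est) - lip_width(hand),
      aperture_diff = lip_aperture(est, n) - lip_aperture(hand, n),
      rounding_hand = lip_rounding(hand),
      rounding_est = lip_rounding(est)
    ),
    class = "lip_eval_frame"
  )
}
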
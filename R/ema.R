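# Electromagnetic articulography (EMA) vs keypoint comparison. EMA coils on
# the tongue tip (TT), blade (TBl) and dorsum (TD) give mm-scale flesh-point
# trajectories at a high sampling rate; the matching estimated keypoints
# (tip1, blade1, dorsum1) are available only at ultrasound frame times. Both
# modalities are rotated into a shared bite-plane coordinate frame, the EMA
# is linearly resampled at the frame times, and agreement is summarized as
# per-coordinate Pearson correlations.

#' Map from EMA sensor names to tongue keypoint names
#' @export
ema_sensor_keypoints <- c(TT = "tip1", TBl = "blade1", TD = "dorsum1")

#' Construct an EMA sensor trajectory
#'
#' @param sensor Sensor name (`"TT"`, `"TBl"` or `"TD"`).
#' @param times Sample times in seconds, strictly increasing.
#' @param x,y Sensor coordinates in mm, same length as `times`.
#' @return An object of class `sensor_trajectory`.
#' @export
sensor_trajectory <- function(sensor, times, x, y) {
  if (length(times) != length(x) || length(times) != length(y)) {
    stop("times, x and y must have equal lengths")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(
    list(
      sensor = sensor, times = as.numeric(times),
      x = as.numeric(x), y = as.numeric(y)
    ),
    class = "sensor_trajectory"
  )
}

#' Define a bite plane by two points on its trace
#'
#' The occlusal (bite) plane is recorded in each modality as a fiducial
#' line; rotating each data set so this line becomes the horizontal axis
#' puts EMA and image coordinates in a shared anatomical frame.
#'
#' @param p1,p2 Distinct length-2 points on the plane's trace.
#' @return A 2 x 2 matrix of class `bite_plane` (rows p1, p2).
#' @export
bite_plane <- function(p1, p2) {
  m <- rbind(p1, p2)
  if (all(m[1L, ] == m[2L, ])) stop("bite plane points must be distinct")
  structure(m, class = c("bite_plane", "matrix"))
}

#' Rotate data into the bite-plane coordinate frame
#'
#' Applies the rigid motion that maps the bite plane's trace onto the
#' horizontal axis: a rotation about the plane's first point followed by a
#' vertical shift, so every point on the trace ends at y = 0. Pairwise
#' distances are preserved.
#'
#' @param points A two-column point matrix, a length-2 vector, or a
#'   [sensor_trajectory()].
#' @param plane A [bite_plane()].
#' @return The aligned object, same shape as the input.
#' @export
align_to_bite_plane <- function(points, plane) {
  if (!inherits(plane, "bite_plane")) plane <- bite_plane(plane[1L, ], plane[2L, ])
  p1 <- as.numeric(plane[1L, ])
  p2 <- as.numeric(plane[2L, ])
  theta <- atan2(p2[2L] - p1[2L], p2[1L] - p1[1L])
  shift <- c(0, -p1[2L])
  if (inherits(points, "sensor_trajectory")) {
    m <- rotate_points(cbind(points$x, points$y), -theta, origin = p1)
    points$x <- m[, 1L] + shift[1L]
    points$y <- m[, 2L] + shift[2L]
    return(points)
  }
  vec <- is.null(dim(points)) && length(points) == 2L
  m <- rotate_points(points, -theta, origin = p1)
  if (vec) m + shift else sweep(m, 2L, -shift)
}

#' Resample a sensor trajectory at ultrasound frame times
#'
#' Linear interpolation of the sensor's x and y at each requested time.
#' EMA sampling rates are far above articulatory bandwidth, so linear
#' interpolation over one EMA sample interval is essentially exact.
#'
#' @param traj A [sensor_trajectory()].
#' @param frame_times Times (seconds) at which to sample; must lie within
#'   the trajectory's time span.
#' @return Matrix with columns `x`, `y`, one row per frame time.
#' @export
resample_to_frames <- function(traj, frame_times) {
  lo <- min(traj$times)
  hi <- max(traj$times)
  out <- which(frame_times < lo | frame_times > hi)
  if (length(out)) {
    stop(sprintf(
      "frame time %.6g s outside trajectory span [%.6g, %.6g]",
      frame_times[out[1L]], lo, hi
    ))
  }
  cbind(
    x = stats::approx(traj$times, traj$x, xout = frame_times)$y,
    y = stats::approx(traj$times, traj$y, xout = frame_times)$y
  )
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation with explicit preconditions: equal lengths,
#' at least 3 paired observations, and non-constant inputs (the coefficient
#' is undefined for a constant series).
#'
#' @param x,y Numeric vectors.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal lengths")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  stats::cor(x, y)
}

#' Pair aligned EMA and keypoint positions at frame times
#'
#' @param sensor Sensor name.
#' @param frame_times Frame times in seconds.
#' @param ema_xy,kp_xy Matrices (n x 2) of aligned EMA and keypoint
#'   positions at those times.
#' @param recording_id Optional recording identifier (used when pooling).
#' @return An object of class `aligned_pair`.
#' @export
aligned_pair <- function(sensor, frame_times, ema_xy, kp_xy,
                         recording_id = "recording") {
  if (nrow(ema_xy) != length(frame_times) || nrow(kp_xy) != length(frame_times)) {
    stop("frame_times, ema_xy and kp_xy must have matching lengths")
  }
  structure(
    list(
      sensor = sensor, frame_times = frame_times,
      ema_xy = ema_xy, kp_xy = kp_xy, recording_id = recording_id
    ),
    class = "aligned_pair"
  )
}

#' Per-sensor, per-coordinate correlation between EMA and keypoints
#'
#' Computes the Pearson correlation between EMA and keypoint positions for
#' each sensor and coordinate (x, y). By default frames are concatenated
#' across recordings before correlating (one pooled scatter per sensor and
#' coordinate); with `per_recording = TRUE` a per-recording table is
#' returned instead.
#'
#' @param pairs List of [aligned_pair()] objects.
#' @param per_recording Logical; report one row per recording instead of
#'   pooling (default `FALSE`).
#' @return Data frame with columns `sensor`, `coord`, `r`, `n` (and
#'   `recording_id` in per-recording mode).
#' @export
correlate_sensors <- function(pairs, per_recording = FALSE) {
  if (!length(pairs)) stop("no aligned pairs supplied")
  if (inherits(pairs, "aligned_pair")) pairs <- list(pairs)
  rows <- list()
  if (per_recording) {
    for (p in pairs) {
      for (ci in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          recording_id = p$recording_id, sensor = p$sensor,
          coord = c("x", "y")[ci],
          r = pearson_r(p$ema_xy[, ci], p$kp_xy[, ci]),
          n = nrow(p$ema_xy), stringsAsFactors = FALSE
        )
      }
    }
  } else {
    sensors <- unique(vapply(pairs, function(p) p$sensor, character(1)))
    for (s in sensors) {
      sel <- Filter(function(p) identical(p$sensor, s), pairs)
      ema <- do.call(rbind, lapply(sel, function(p) p$ema_xy))
      kp <- do.call(rbind, lapply(sel, function(p) p$kp_xy))
      for (ci in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          sensor = s, coord = c("x", "y")[ci],
          r = pearson_r(ema[, ci], kp[, ci]),
          n = nrow(ema), stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Read and write EMA trajectory tables
#'
#' The on-disk form is a comma- or tab-separated table with columns
#' `time_s`, `sensor`, `x_mm`, `y_mm` (and optionally `recording_id`), one
#' row per sample.
#'
#' @param path File path.
#' @return For `read_ema_table`, a named list: one list per recording id,
#'   each holding one [sensor_trajectory()] per sensor.
#' @export
read_ema_table <- function(path) {
  if (!file.exists(path)) stop("EMA table not found: ", path)
  df <- utils::read.delim(path,
    sep = if (grepl("\\.csv$", path)) "," else "\t",
    stringsAsFactors = FALSE
  )
  req <- c("time_s", "sensor", "x_mm", "y_mm")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("EMA table missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$recording_id)) df$recording_id <- "recording"
  out <- list()
  for (rid in unique(df$recording_id)) {
    sub <- df[df$recording_id == rid, ]
    trajs <- list()
    for (s in unique(sub$sensor)) {
      ss <- sub[sub$sensor == s, ]
      o <- order(ss$time_s)
      trajs[[s]] <- sensor_trajectory(s, ss$time_s[o], ss$x_mm[o], ss$y_mm[o])
    }
    out[[rid]] <- trajs
  }
  out
}

#' @rdname read_ema_table
#' @param trajectories Named list of recordings, each a named list of
#'   [sensor_trajectory()] (the form returned by `read_ema_table`), or a
#'   plain list of trajectories for a single recording.
#' @export
write_ema_table <- function(trajectories, path) {
  if (length(trajectories) && inherits(trajectories[[1L]], "sensor_trajectory")) {
    trajectories <- list(recording = trajectories)
  }
  rows <- list()
  for (rid in names(trajectories)) {
    for (tr in trajectories[[rid]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        recording_id = rid, time_s = tr$times, sensor = tr$sensor,
        x_mm = tr$x, y_mm = tr$y, stringsAsFactors = FALSE
      )
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
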
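# Synthetic-data generators. These stand in for ultrasound/camera/EMA
# recordings: a tongue-like contour family (circular fan arc plus Gaussian
# bumps, emulating root/dorsum/blade gestures), lip frames with the A-H
# placement rules, labeller/estimator noise, and paired high-rate sensor /
# frame-rate keypoint sessions sharing latent motion. The shapes are
# synthetic, not anatomical: they reproduce the geometry the metrics need
# (convex-up contour, denser blade/tip keypoints, commissure-anchored lip
# arcs), nothing more.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random state. seed = NULL means "use the ambient RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  force(code)
}

#' Tongue contour shape parameters
#'
#' The synthetic tongue contour is a fan-coordinate curve around a virtual
#' probe origin: radius `base_radius` plus Gaussian bumps at the root,
#' dorsum and blade regions, traced from the vallecula (posterior) to the
#' tip (anterior). With all bump amplitudes zero the contour is a circular
#' arc of radius `base_radius`.
#'
#' @param fan_origin Virtual probe centre in mm (image convention, y down).
#' @param base_radius Arc radius in mm (> 0).
#' @param angular_span Angular extent of the contour in radians, in
#'   (0, pi).
#' @param bump_amplitudes Maximum bump amplitudes in mm for the root,
#'   dorsum and blade gestures; actual amplitudes are drawn uniformly in
#'   +/- each value.
#' @param seed Integer seed, or `NULL` to draw from the ambient RNG.
#' @return List of class `tongue_shape_params`.
#' @export
tongue_shape_params <- function(fan_origin = c(80, 115), base_radius = 50,
                                angular_span = 2.36,
                                bump_amplitudes = c(root = 3, dorsum = 5, blade = 4),
                                seed = NULL) {
  if (base_radius <= 0) stop("base_radius must be positive")
  if (angular_span <= 0 || angular_span >= pi) {
    stop("angular_span must lie in (0, pi)")
  }
  structure(
    list(
      fan_origin = fan_origin, base_radius = base_radius,
      angular_span = angular_span, bump_amplitudes = bump_amplitudes,
      seed = seed
    ),
    class = "tongue_shape_params"
  )
}

# Dense sample of the fan-coordinate contour for given bump amplitudes.
.tongue_curve <- function(params, amps, n_dense = 400L) {
  t <- seq(0, 1, length.out = n_dense)
  centers <- c(0.25, 0.55, 0.85)
  width <- 0.10
  r <- rep(params$base_radius, n_dense)
  for (k in seq_along(amps)) {
    r <- r + amps[k] * exp(-(t - centers[k])^2 / (2 * width^2))
  }
  # theta runs posterior (vallecula) to anterior (tip); -sin gives "up" in
  # image coordinates (y increases downward)
  theta_start <- pi / 2 + params$angular_span / 2
  theta <- theta_start - t * params$angular_span
  cbind(
    x = params$fan_origin[1L] + r * cos(theta),
    y = params$fan_origin[2L] - r * sin(theta)
  )
}

# Arc-length positions of the 11 tongue keypoints: gaps between the
# vallecula..blade1 points have unit weight and the three blade/tip gaps
# half weight, so consecutive blade/tip separation is about half that of
# the other points.
.tongue_kp_fractions <- function() {
  w <- c(rep(1, 7), rep(0.5, 3))
  c(0, cumsum(w)) / sum(w)
}

#' Generate one synthetic tongue frame
#'
#' Produces a smooth ground-truth contour (in mm) and the 11 tongue-surface
#' keypoints placed on it in anatomical order at arc-length positions whose
#' blade/tip spacing is about half the root/dorsum spacing, plus the hyoid,
#' mandible-base and short-tendon reference points at fixed offsets from
#' the fan origin. Keypoints coincide with samples of the returned truth
#' curve, so their distance to it is exactly zero before any perturbation.
#'
#' @param params A [tongue_shape_params()].
#' @param frame_index Frame number recorded on the keypoint frame.
#' @param n_dense Dense sample count for the truth curve (default 400).
#' @return List with `truth` (dense curve matrix, mm) and `keypoints`
#'   (a [frame_keypoints()] in mm, confidence 1).
#' @export
gen_tongue_frame <- function(params = tongue_shape_params(), frame_index = 0L,
                             n_dense = 400L) {
  with_seed(params$seed, {
    amps <- vapply(params$bump_amplitudes, function(a) {
      if (a == 0) 0 else stats::runif(1, -a, a)
    }, numeric(1))
    truth <- .tongue_curve(params, amps, n_dense)
    seg <- sqrt(rowSums((truth[-1L, ] - truth[-nrow(truth), ])^2))
    cum <- c(0, cumsum(seg))
    targets <- .tongue_kp_fractions() * cum[length(cum)]
    idx <- vapply(targets, function(s) which.min(abs(cum - s)), integer(1))
    kp_xy <- truth[idx, , drop = FALSE]
    ref_xy <- rbind(
      hyoid = params$fan_origin + c(-30, -8),
      mandibleBase = params$fan_origin + c(38, -5),
      shortTendon = params$fan_origin + c(42, -14)
    )
    kp <- frame_keypoints(
      c(tongue_keypoints, reference_keypoints),
      c(kp_xy[, 1L], ref_xy[, 1L]),
      c(kp_xy[, 2L], ref_xy[, 2L]),
      confidence = 1,
      frame_index = frame_index
    )
    list(truth = truth, keypoints = kp)
  })
}

#' Labeller/estimator noise model
#'
#' Keypoint jitter is decomposed relative to the local contour direction:
#' `sigma_normal_mm` perpendicular to the tangent (the component the MSD
#' sees) and `sigma_tangent_mm` along it (absorbed by nearest-point
#' matching). With probability `dropout_prob` a keypoint is emitted with
#' confidence `low_conf_value` (so a standard cutoff removes it);
#' otherwise confidence is drawn uniformly in (0.8, 1).
#'
#' @param sigma_normal_mm,sigma_tangent_mm Jitter scales in mm (>= 0).
#' @param dropout_prob Probability of a low-confidence keypoint.
#' @param low_conf_value Confidence assigned to dropped-out keypoints.
#' @param seed Integer seed or `NULL`.
#' @return List of class `noise_model`.
#' @export
noise_model <- function(sigma_normal_mm = 0.5, sigma_tangent_mm = 1,
                        dropout_prob = 0, low_conf_value = 0.3, seed = NULL) {
  if (sigma_normal_mm < 0 || sigma_tangent_mm < 0) stop("sigmas must be >= 0")
  if (dropout_prob < 0 || dropout_prob > 1) stop("dropout_prob must be in [0, 1]")
  structure(
    list(
      sigma_normal_mm = sigma_normal_mm, sigma_tangent_mm = sigma_tangent_mm,
      dropout_prob = dropout_prob, low_conf_value = low_conf_value, seed = seed
    ),
    class = "noise_model"
  )
}

# Unit tangents of a dense curve by central differences.
.curve_tangents <- function(curve) {
  n <- nrow(curve)
  d <- rbind(
    curve[2L, ] - curve[1L, ],
    curve[3:n, , drop = FALSE] - curve[1:(n - 2L), , drop = FALSE],
    curve[n, ] - curve[n - 1L, ]
  )
  d / sqrt(rowSums(d^2))
}

#' Perturb keypoints with tangent-decomposed jitter and dropout
#'
#' Displaces each keypoint by independent normal jitter perpendicular to
#' and along the local tangent of the truth curve (the nearest truth sample
#' supplies the tangent), then assigns confidences per the noise model.
#' Keypoints far from the truth curve (the fixed reference points) receive
#' isotropic jitter of the same scales.
#'
#' @param frame A [frame_keypoints()] whose points lie near `truth`.
#' @param truth Dense truth curve matrix.
#' @param noise A [noise_model()].
#' @return The perturbed `frame_keypoints`.
#' @export
perturb_keypoints <- function(frame, truth, noise = noise_model()) {
  with_seed(noise$seed, {
    tang <- .curve_tangents(truth)
    n <- nrow(frame)
    en <- stats::rnorm(n, 0, noise$sigma_normal_mm)
    et <- stats::rnorm(n, 0, noise$sigma_tangent_mm)
    for (i in seq_len(n)) {
      nd <- nearest_distance(c(frame$x[i], frame$y[i]), truth)
      tv <- tang[nd$index, ]
      nv <- c(-tv[2L], tv[1L])
      frame$x[i] <- frame$x[i] + et[i] * tv[1L] + en[i] * nv[1L]
      frame$y[i] <- frame$y[i] + et[i] * tv[2L] + en[i] * nv[2L]
    }
    drop <- stats::runif(n) < noise$dropout_prob
    conf <- stats::runif(n, 0.8, 1)
    conf[drop] <- noise$low_conf_value
    frame$confidence <- conf
    frame
  })
}

#' Displace a curve along its local normals
#'
#' Shifts every sample of a curve by a constant signed distance `d` along
#' the local unit normal (computed by central differences). For a smooth
#' curve this produces a parallel curve at distance `|d|`, the construction
#' under which the modified MSD recovers `|d|` exactly; drawing
#' `d ~ N(0, sigma^2)` per frame therefore yields a mean MSD of
#' `sigma * sqrt(2/pi)` over many frames.
#'
#' @param curve Curve matrix (or a [frame_keypoints()], in which case its
#'   points are displaced along the normals of `ref`).
#' @param d Signed offset in curve units.
#' @param ref Curve supplying the tangent field (defaults to `curve`).
#' @return The displaced curve (same type as the input).
#' @export
offset_curve_normal <- function(curve, d, ref = NULL) {
  is_frame <- inherits(curve, "frame_keypoints")
  if (is.null(ref)) {
    if (is_frame) stop("ref curve required when displacing keypoints")
    ref <- curve
  }
  tang <- .curve_tangents(.as_xy(ref))
  if (is_frame) {
    for (i in seq_len(nrow(curve))) {
      nd <- nearest_distance(c(curve$x[i], curve$y[i]), ref)
      tv <- tang[nd$index, ]
      curve$x[i] <- curve$x[i] - d * tv[2L]
      curve$y[i] <- curve$y[i] + d * tv[1L]
    }
    return(curve)
  }
  m <- .as_xy(curve)
  cbind(
    x = m[, 1L] - d * tang[, 2L],
    y = m[, 2L] + d * tang[, 1L]
  )
}

#' Lip frame shape parameters
#'
#' Synthetic lip frames place the commissures A and B `width_mm` apart and
#' the upper/lower midline points C and D on two elliptical arcs of heights
#' `upper_height_mm` and `lower_height_mm`; E/G and F/H sit at the arc
#' midpoints between the commissures and the midline points. `asymmetry`
#' is the standard deviation (mm) of a horizontal offset applied to C and D
#' (the philtrum midline need not be equidistant from the commissures).
#'
#' @param width_mm Commissure separation in mm (> 0).
#' @param upper_height_mm,lower_height_mm Arc heights in mm (>= 0).
#' @param asymmetry Sd of the C/D horizontal offset in mm.
#' @param height_jitter Relative uniform jitter applied to the heights
#'   (0 disables).
#' @param seed Integer seed or `NULL`.
#' @return List of class `lip_shape_params`.
#' @export
lip_shape_params <- function(width_mm = 50, upper_height_mm = 8,
                             lower_height_mm = 10, asymmetry = 0,
                             height_jitter = 0, seed = NULL) {
  if (width_mm <= 0) stop("width_mm must be positive")
  if (upper_height_mm < 0 || lower_height_mm < 0) stop("heights must be >= 0")
  structure(
    list(
      width_mm = width_mm, upper_height_mm = upper_height_mm,
      lower_height_mm = lower_height_mm, asymmetry = asymmetry,
      height_jitter = height_jitter, seed = seed
    ),
    class = "lip_shape_params"
  )
}

#' Generate one synthetic lip frame
#'
#' Points lie on two half-ellipse arcs sharing the commissures: the upper
#' arc through A, E, C, G, B (heights measured upward, i.e. toward negative
#' y in image convention) and the lower arc through A, F, D, H, B. E/F/G/H
#' are at the 45-degree arc positions, midway between commissures and
#' midline points; C and D may be offset horizontally by the asymmetry
#' draw. Heights of zero give a degenerate closed mouth with zero aperture.
#'
#' @param params A [lip_shape_params()].
#' @param frame_index Frame number recorded on the frame.
#' @return A lip [frame_keypoints()] in mm.
#' @export
gen_lip_frame <- function(params = lip_shape_params(), frame_index = 0L) {
  with_seed(params$seed, {
    jit <- function(h) {
      if (params$height_jitter == 0 || h == 0) return(h)
      h * stats::runif(1, 1 - params$height_jitter, 1 + params$height_jitter)
    }
    uh <- jit(params$upper_height_mm)
    lh <- jit(params$lower_height_mm)
    off <- if (params$asymmetry > 0) stats::rnorm(1, 0, params$asymmetry) else 0
    a <- params$width_mm / 2
    arc <- function(t, h, sgn) c(a * cos(t), sgn * h * sin(t))
    pts <- rbind(
      A = c(-a, 0), B = c(a, 0),
      C = arc(pi / 2, uh, -1) + c(off, 0),
      D = arc(pi / 2, lh, +1) + c(off, 0),
      E = arc(3 * pi / 4, uh, -1),
      G = arc(pi / 4, uh, -1),
      F = arc(3 * pi / 4, lh, +1),
      H = arc(pi / 4, lh, +1)
    )
    lip_frame(pts, frame_index = frame_index)
  })
}

#' Motion parameters for a paired EMA/keypoint session
#'
#' The latent 2-D motion of each sensor is a sum of sinusoids at
#' `latent_frequencies` with amplitudes `latent_amplitudes` and random
#' phases (per sensor, coordinate and harmonic). The EMA channel samples
#' the latent motion at `ema_rate_hz` with noise `sigma_ema_mm`; the
#' keypoint channel samples it at `frame_rate_hz` with noise
#' `sigma_kp_mm`, optionally rotated by `rotation_deg` (to be undone by
#' bite-plane alignment). With `decouple_x = TRUE` the keypoint x
#' coordinate follows an independent latent, emulating the empirical
#' pattern that vertical sensor motion is tracked much better than
#' horizontal.
#'
#' @param duration_s Session length in seconds.
#' @param ema_rate_hz,frame_rate_hz Sampling rates; `ema_rate_hz` must
#'   exceed `frame_rate_hz`.
#' @param latent_frequencies,latent_amplitudes Hz / mm vectors of equal
#'   length. The latent variance per coordinate is
#'   `sum(latent_amplitudes^2) / 2`.
#' @param sigma_ema_mm,sigma_kp_mm Additive white-noise scales.
#' @param rotation_deg Fixed rotation applied to the keypoint modality.
#' @param decouple_x Logical (see above).
#' @param seed Integer seed or `NULL`.
#' @return List of class `motion_params`.
#' @export
motion_params <- function(duration_s = 10, ema_rate_hz = 250,
                          frame_rate_hz = 81.25,
                          latent_frequencies = c(0.9, 2.1, 3.4),
                          latent_amplitudes = c(5, 2.5, 1.2),
                          sigma_ema_mm = 0, sigma_kp_mm = 0,
                          rotation_deg = 0, decouple_x = FALSE, seed = NULL) {
  if (!(ema_rate_hz > frame_rate_hz && frame_rate_hz > 0)) {
    stop("need ema_rate_hz > frame_rate_hz > 0")
  }
  if (length(latent_frequencies) != length(latent_amplitudes)) {
    stop("latent_frequencies and latent_amplitudes must have equal lengths")
  }
  structure(
    list(
      duration_s = duration_s, ema_rate_hz = ema_rate_hz,
      frame_rate_hz = frame_rate_hz,
      latent_frequencies = latent_frequencies,
      latent_amplitudes = latent_amplitudes,
      sigma_ema_mm = sigma_ema_mm, sigma_kp_mm = sigma_kp_mm,
      rotation_deg = rotation_deg, decouple_x = decouple_x, seed = seed
    ),
    class = "motion_params"
  )
}

#' Generate a paired EMA/keypoint session
#'
#' Simulates one simultaneous recording: three sensors (TT, TBl, TD) with
#' shared latent motion observed through a high-rate noisy EMA channel and
#' a frame-rate noisy keypoint channel (keypoints tip1, blade1, dorsum1).
#' Both modalities carry a bite plane; the keypoint modality's plane is
#' rotated together with its data so that [align_to_bite_plane()] restores
#' the shared frame.
#'
#' @param params A [motion_params()].
#' @param recording_id Identifier for the session.
#' @return List with `ema` (named list of [sensor_trajectory()]),
#'   `keypoints` (a [recording()] in mm with `fps = frame_rate_hz`),
#'   `bite_plane_ema`, `bite_plane_kp` ([bite_plane()] objects) and
#'   `latent_var` (per-coordinate latent variance, mm^2).
#' @export
gen_ema_session <- function(params = motion_params(), recording_id = "session") {
  with_seed(params$seed, {
    sensors <- names(ema_sensor_keypoints)
    centers <- list(TT = c(60, 40), TBl = c(45, 45), TD = c(30, 50))
    t_ema <- seq(0, params$duration_s, by = 1 / params$ema_rate_hz)
    t_kp <- seq(0, params$duration_s, by = 1 / params$frame_rate_hz)
    t_kp <- t_kp[t_kp <= max(t_ema)]
    latent <- function(tt, phases, freqs = params$latent_frequencies) {
      v <- numeric(length(tt))
      for (k in seq_along(freqs)) {
        v <- v + params$latent_amplitudes[k] *
          sin(2 * pi * freqs[k] * tt + phases[k])
      }
      v
    }
    # an independent latent must not share harmonics with the shared one,
    # or residual correlation survives arbitrarily long windows
    freq_indep <- params$latent_frequencies * (1 + sqrt(2)) / 2
    nh <- length(params$latent_frequencies)
    ema <- list()
    kp_xy <- list()
    for (s in sensors) {
      ph_x <- stats::runif(nh, 0, 2 * pi)
      ph_y <- stats::runif(nh, 0, 2 * pi)
      ph_x_kp <- if (params$decouple_x) stats::runif(nh, 0, 2 * pi) else ph_x
      ex <- centers[[s]][1L] + latent(t_ema, ph_x) +
        stats::rnorm(length(t_ema), 0, params$sigma_ema_mm)
      ey <- centers[[s]][2L] + latent(t_ema, ph_y) +
        stats::rnorm(length(t_ema), 0, params$sigma_ema_mm)
      ema[[s]] <- sensor_trajectory(s, t_ema, ex, ey)
      kx <- centers[[s]][1L] +
        latent(t_kp, ph_x_kp,
          if (params$decouple_x) freq_indep else params$latent_frequencies
        ) +
        stats::rnorm(length(t_kp), 0, params$sigma_kp_mm)
      ky <- centers[[s]][2L] + latent(t_kp, ph_y) +
        stats::rnorm(length(t_kp), 0, params$sigma_kp_mm)
      kp_xy[[s]] <- cbind(x = kx, y = ky)
    }
    rot <- params$rotation_deg * pi / 180
    plane_kp <- bite_plane(c(0, 0), c(30, 0))
    if (rot != 0) {
      for (s in sensors) kp_xy[[s]] <- rotate_points(kp_xy[[s]], rot)
      plane_kp <- bite_plane(
        rotate_points(c(0, 0), rot),
        rotate_points(c(30, 0), rot)
      )
    }
    frames <- lapply(seq_along(t_kp), function(i) {
      frame_keypoints(
        unname(ema_sensor_keypoints),
        vapply(sensors, function(s) kp_xy[[s]][i, 1L], numeric(1)),
        vapply(sensors, function(s) kp_xy[[s]][i, 2L], numeric(1)),
        confidence = 1, frame_index = i - 1L, time_s = t_kp[i]
      )
    })
    list(
      ema = ema,
      keypoints = recording(frames, recording_id, fps = params$frame_rate_hz,
        scale = scale_info(mm_per_pixel = 1)
      ),
      bite_plane_ema = bite_plane(c(0, 0), c(30, 0)),
      bite_plane_kp = plane_kp,
      latent_var = sum(params$latent_amplitudes^2) / 2
    )
  })
}

#' Write a synthetic paired hand/estimate keypoint corpus to disk
#'
#' Generates `n_recordings` recordings of `frames_per_recording` frames
#' each and writes them as paired DeepLabCut-style CSVs plus per-recording
#' metadata under `dir/hand` and `dir/est` (file names
#' `spk<NN>.csv` / `spk<NN>.yaml`). Hand frames are the exact on-curve
#' keypoints (confidence 1); estimated frames are displaced by a per-frame
#' perpendicular offset `d ~ N(0, sigma_offset_mm^2)` of the whole contour
#' and optionally by per-keypoint jitter and low-confidence dropout.
#' Coordinates are stored in pixels at the per-recording scale recorded in
#' the metadata. The corpus layout (recordings x frames) mirrors a
#' multi-speaker test set, e.g. 25 x 40 = 1000 evaluation frames.
#'
#' @param dir Output directory (created if needed).
#' @param n_recordings,frames_per_recording Corpus shape (>= 1 each).
#' @param seed Integer seed; the whole tree is a deterministic function of
#'   it.
#' @param kind `"tongue"` (default) or `"lip"`.
#' @param sigma_offset_mm Sd of the per-frame perpendicular contour offset
#'   (tongue corpora). The default 1.25 mm is calibrated so the corpus mean
#'   modified MSD lands near 1 mm (`1.25 * sqrt(2/pi) = 0.997`), the
#'   magnitude of typical inter-labeller disagreement.
#' @param noise Optional [noise_model()] for additional per-keypoint
#'   jitter/dropout on the estimates (`NULL` for none).
#' @param sigma_lip_mm Per-keypoint isotropic jitter for lip corpora.
#' @param fps Frame rate written to the metadata.
#' @param field_height_mm,image_height_px Per-recording scale metadata
#'   (0.5 mm/px by default).
#' @return Invisibly, a list with the corpus paths and the total frame
#'   count.
#' @export
gen_fixture_corpus <- function(dir, n_recordings = 25L,
                               frames_per_recording = 40L, seed = 1L,
                               kind = c("tongue", "lip"),
                               sigma_offset_mm = 1.25, noise = NULL,
                               sigma_lip_mm = 0.5, fps = 81.25,
                               field_height_mm = 120, image_height_px = 240) {
  kind <- match.arg(kind)
  if (n_recordings < 1L || frames_per_recording < 1L) {
    stop("n_recordings and frames_per_recording must be >= 1")
  }
  hand_dir <- file.path(dir, "hand")
  est_dir <- file.path(dir, "est")
  dir.create(hand_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(est_dir, recursive = TRUE, showWarnings = FALSE)
  mm_per_px <- field_height_mm / image_height_px
  with_seed(seed, {
    for (r in seq_len(n_recordings)) {
      rid <- sprintf("spk%02d", r)
      hand_frames <- vector("list", frames_per_recording)
      est_frames <- vector("list", frames_per_recording)
      for (f in seq_len(frames_per_recording)) {
        fi <- f - 1L
        if (kind == "tongue") {
          tf <- gen_tongue_frame(tongue_shape_params(seed = NULL),
            frame_index = fi
          )
          hand <- tf$keypoints
          d <- stats::rnorm(1, 0, sigma_offset_mm)
          est <- offset_curve_normal(hand, d, ref = tf$truth)
          if (!is.null(noise)) est <- perturb_keypoints(est, tf$truth, noise)
          else est$confidence <- stats::runif(nrow(est), 0.8, 1)
        } else {
          hand <- gen_lip_frame(
            lip_shape_params(asymmetry = 2, height_jitter = 0.3, seed = NULL),
            frame_index = fi
          )
          est <- hand
          est$x <- est$x + stats::rnorm(nrow(est), 0, sigma_lip_mm)
          est$y <- est$y + stats::rnorm(nrow(est), 0, sigma_lip_mm)
          est$confidence <- stats::runif(nrow(est), 0.8, 1)
        }
        # store in pixels; lip frames are centred on the image
        shift <- if (kind == "lip") c(80, 60) else c(0, 0)
        px <- function(fr) {
          fr$x <- (fr$x + shift[1L]) / mm_per_px
          fr$y <- (fr$y + shift[2L]) / mm_per_px
          fr
        }
        hand_frames[[f]] <- px(hand)
        est_frames[[f]] <- px(est)
      }
      meta <- list(
        recording_id = rid, fps = fps,
        field_height_mm = field_height_mm, image_height_px = image_height_px
      )
      write_dlc_csv(
        recording(hand_frames, rid, fps),
        file.path(hand_dir, paste0(rid, ".csv"))
      )
      write_dlc_csv(
        recording(est_frames, rid, fps),
        file.path(est_dir, paste0(rid, ".csv"))
      )
      write_recording_meta(meta, file.path(hand_dir, paste0(rid, ".yaml")))
      write_recording_meta(meta, file.path(est_dir, paste0(rid, ".yaml")))
    }
  })
  invisible(list(
    hand = hand_dir, est = est_dir,
    n_frames = n_recordings * frames_per_recording
  ))
}
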
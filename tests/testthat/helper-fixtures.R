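# Shared fixtures and independent oracles used across the test files.

# A random recording with arbitrary keypoint names and confidences,
# including occasional missing cells, for round-trip tests.
random_recording <- function(n_frames = 3, n_kp = 4, missing_prob = 0.1) {
  nm <- paste0("kp", seq_len(n_kp))
  frames <- lapply(seq_len(n_frames), function(i) {
    x <- runif(n_kp, 0, 320)
    y <- runif(n_kp, 0, 240)
    conf <- runif(n_kp)
    drop <- runif(n_kp) < missing_prob
    x[drop] <- NA
    y[drop] <- NA
    conf[drop] <- 0
    frame_keypoints(nm, x, y, conf, frame_index = i - 1L)
  })
  recording(frames, "fixture", fps = 81.25)
}

# A smooth random open curve: low-order Fourier perturbation of an arc.
random_smooth_curve <- function(n = 100, radius = 50, span = 2.2) {
  t <- seq(0, 1, length.out = n)
  r <- radius + 3 * sin(2 * pi * runif(1) + 2 * pi * t * sample(1:3, 1)) +
    2 * sin(2 * pi * runif(1) + 2 * pi * t * sample(1:2, 1))
  th <- pi / 2 + span / 2 - t * span
  cbind(x = r * cos(th), y = -r * sin(th))
}

# Independent brute-force implementation of the modified MSD endpoint rule,
# written directly from its definition over plain loops. Optionally
# evaluates the curves at `dense` times the nominal sampling.
brute_msd_modified <- function(A, B) {
  directed <- function(S, T) {
    nT <- nrow(T)
    d <- numeric(nrow(S))
    j <- integer(nrow(S))
    for (i in seq_len(nrow(S))) {
      dd <- sqrt((T[, 1] - S[i, 1])^2 + (T[, 2] - S[i, 2])^2)
      j[i] <- which.min(dd)
      d[i] <- dd[j[i]]
    }
    keep <- d[j != 1 & j != nT]
    for (e in unique(c(1L, nT))) {
      de <- d[j == e]
      if (length(de)) keep <- c(keep, min(de))
    }
    keep
  }
  da <- directed(A, B)
  db <- directed(B, A)
  (sum(da) + sum(db)) / (length(da) + length(db))
}

# The worked 8-point lip configuration whose rounding index is 0.15.
worked_lip_frame <- function() {
  lip_frame(rbind(
    A = c(0, 0), B = c(40, 0), C = c(20, 10), D = c(20, -10),
    E = c(10, 7), F = c(10, -7), G = c(30, 7), H = c(30, -7)
  ))
}

tongue_only <- function(frame) {
  out <- frame[frame$name %in% tongue_keypoints, , drop = FALSE]
  structure(out,
    frame_index = attr(frame, "frame_index"),
    class = c("frame_keypoints", "data.frame")
  )
}

# Build the per-sensor aligned pairs of a generated session without the
# run_ema_eval driver (used to test correlate_sensors in isolation).
session_pairs <- function(session) {
  tf <- vapply(session$keypoints$frames, function(f) attr(f, "time_s"), numeric(1))
  lapply(names(session$ema), function(sn) {
    exy <- resample_to_frames(session$ema[[sn]], tf)
    kname <- ema_sensor_keypoints[[sn]]
    kxy <- t(vapply(session$keypoints$frames, function(f) {
      i <- match(kname, f$name)
      c(f$x[i], f$y[i])
    }, numeric(2)))
    aligned_pair(sn, tf, exy, kxy, recording_id = session$keypoints$recording_id)
  })
}
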
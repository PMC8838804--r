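# Corpus-level evaluation drivers: tongue contours, lip measures and
# EMA/keypoint correlation. A "corpus" is a directory of DeepLabCut-style
# CSVs (one per recording) with sibling <recording>.yaml metadata giving
# fps and the pixel-to-mm scale. Hand and estimate corpora are matched by
# file name and frame index; unmatched material is skipped with a warning
# and counted in the result.

.list_corpus <- function(dir) {
  if (!dir.exists(dir)) stop("corpus directory not found: ", dir)
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop("no CSV files in corpus: ", dir)
  files
}

.read_corpus_recording <- function(csv_path) {
  meta_path <- sub("\\.csv$", ".yaml", csv_path)
  if (file.exists(meta_path)) {
    meta <- read_recording_meta(meta_path)
    read_dlc_csv(csv_path,
      recording_id = meta$recording_id, fps = meta$fps,
      scale = meta$scale
    )
  } else {
    message("no metadata for ", basename(csv_path), "; assuming 1 mm per pixel")
    read_dlc_csv(csv_path, scale = scale_info(mm_per_pixel = 1))
  }
}

.match_corpora <- function(hand_dir, est_dir) {
  hand_files <- .list_corpus(hand_dir)
  est_files <- .list_corpus(est_dir)
  hb <- basename(hand_files)
  eb <- basename(est_files)
  shared <- intersect(hb, eb)
  if (!length(shared)) stop("no recordings shared between hand and est corpora")
  unmatched <- c(setdiff(hb, eb), setdiff(eb, hb))
  if (length(unmatched)) {
    warning(
      "skipping unmatched recordings: ",
      paste(unmatched, collapse = ", ")
    )
  }
  list(
    hand = hand_files[match(shared, hb)],
    est = est_files[match(shared, eb)]
  )
}

#' Evaluate an estimated tongue-contour corpus against hand labels
#'
#' For every frame present in both corpora: converts keypoints to mm using
#' the per-recording scale, builds the 11-control-point cubic tongue spline
#' for the hand labels and for the confidence-filtered estimates, and
#' computes the MSD (modified by default), the signed length difference and
#' the keypoint RMSE in pixels. Frames where fewer than `min_keypoints`
#' tongue keypoints survive the confidence cutoff are skipped (no spline is
#' defined) and counted. Results are aggregated per recording and overall,
#' with frames weighted equally.
#'
#' @param hand_dir,est_dir Corpus directories (see package README for the
#'   layout).
#' @param pcutoff Confidence cutoff for estimated keypoints (default 0.6).
#' @param msd_variant `"modified"` (default) or `"standard"`.
#' @param n_samples Spline sample count for the metrics (default 100).
#' @param min_keypoints Minimum confident tongue keypoints per estimated
#'   frame (default 2).
#' @param reference Optional numeric vector of per-frame MSD values (e.g.
#'   from an inter-labeller run) to t-test each recording's and the overall
#'   MSD distribution against.
#' @param ttest_variant Variance assumption for the reference t-tests.
#' @return Object of class `tongue_eval`: list with `frames` (per-frame
#'   data frame: recording_id, frame_index, msd_mm, n_distances, len_hand_mm,
#'   len_est_mm, diff_mm, pct, rmse_px, n_kp_est), `by_recording` and
#'   `overall` summaries, `skipped` (data frame of skipped frames with
#'   reasons) and optionally `ttest`.
#' @export
run_tongue_eval <- function(hand_dir, est_dir, pcutoff = 0.6,
                            msd_variant = c("modified", "standard"),
                            n_samples = 100L, min_keypoints = 2L,
                            reference = NULL,
                            ttest_variant = c("unequal", "equal")) {
  msd_variant <- match.arg(msd_variant)
  ttest_variant <- match.arg(ttest_variant)
  msd_fun <- if (msd_variant == "modified") msd_modified else msd_standard
  files <- .match_corpora(hand_dir, est_dir)
  rows <- list()
  skipped <- list()
  for (k in seq_along(files$hand)) {
    hrec <- .read_corpus_recording(files$hand[k])
    erec <- .read_corpus_recording(files$est[k])
    hidx <- vapply(hrec$frames, function(f) attr(f, "frame_index"), integer(1))
    eidx <- vapply(erec$frames, function(f) attr(f, "frame_index"), integer(1))
    common <- intersect(hidx, eidx)
    lost <- c(setdiff(hidx, eidx), setdiff(eidx, hidx))
    for (fi in lost) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        recording_id = hrec$recording_id, frame_index = fi,
        reason = "unmatched frame", stringsAsFactors = FALSE
      )
    }
    if (length(lost)) {
      warning(sprintf(
        "%s: %d unmatched frame(s) skipped", hrec$recording_id, length(lost)
      ))
    }
    for (fi in common) {
      hand <- hrec$frames[[match(fi, hidx)]]
      est <- erec$frames[[match(fi, eidx)]]
      hand_t <- hand[match(tongue_keypoints, hand$name), , drop = FALSE]
      hand_t <- hand_t[!is.na(hand_t$name) & is.finite(hand_t$x), , drop = FALSE]
      est_f <- filter_by_confidence(est, pcutoff)
      est_t <- est_f[est_f$name %in% tongue_keypoints, , drop = FALSE]
      est_t <- est_t[order(match(est_t$name, tongue_keypoints)), , drop = FALSE]
      if (nrow(est_t) < min_keypoints || nrow(hand_t) < 2L) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          recording_id = hrec$recording_id, frame_index = fi,
          reason = sprintf(
            "only %d confident tongue keypoint(s)", nrow(est_t)
          ),
          stringsAsFactors = FALSE
        )
        next
      }
      rmse <- rmse_keypoints(hand, est, pcutoff)
      hand_mm <- to_mm(hand_t, hrec$scale)
      est_mm <- to_mm(est_t, erec$scale)
      hc <- interpolate_spline(hand_mm, n_samples)
      ec <- interpolate_spline(est_mm, n_samples)
      m <- msd_fun(hc, ec)
      ld <- length_difference(hc, ec)
      rows[[length(rows) + 1L]] <- data.frame(
        recording_id = hrec$recording_id, frame_index = fi,
        msd_mm = m$msd_mm, n_distances = m$n_distances,
        len_hand_mm = arc_length(hc), len_est_mm = arc_length(ec),
        diff_mm = ld$diff_mm, pct = ld$pct,
        rmse_px = rmse, n_kp_est = nrow(est_t),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) stop("no evaluable frames in the two corpora")
  frames <- do.call(rbind, rows)
  by_rec <- do.call(rbind, lapply(
    split(frames, frames$recording_id),
    function(g) summarize_frames(g, g$recording_id[1L])
  ))
  rownames(by_rec) <- NULL
  overall <- summarize_frames(frames, "overall")
  ttest <- NULL
  if (!is.null(reference)) {
    ttest <- compare_distributions(frames$msd_mm, reference, ttest_variant)
  }
  structure(
    list(
      frames = frames, by_recording = by_rec, overall = overall,
      skipped = if (length(skipped)) do.call(rbind, skipped) else
        data.frame(
          recording_id = character(), frame_index = integer(),
          reason = character(), stringsAsFactors = FALSE
        ),
      ttest = ttest,
      config = list(
        pcutoff = pcutoff, msd_variant = msd_variant,
        n_samples = n_samples, min_keypoints = min_keypoints
      )
    ),
    class = "tongue_eval"
  )
}

#' @export
print.tongue_eval <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    paste0(
      "<tongue_eval> %d frames, %d recordings (%d skipped)\n",
      "  MSD (%s): mean %.3f, sd %.3f, median %.3f mm\n",
      "  %%length diff: mean %+.2f, sd %.2f, median %+.2f\n"
    ),
    o$n_frames, nrow(x$by_recording), nrow(x$skipped),
    x$config$msd_variant, o$msd_mean, o$msd_sd, o$msd_median,
    o$pct_mean, o$pct_sd, o$pct_median
  ))
  if (!is.null(x$ttest)) print(x$ttest)
  invisible(x)
}

#' @export
summary.tongue_eval <- function(object, ...) {
  print(object)
  cat("\nPer-recording summaries:\n")
  print.data.frame(object$by_recording, digits = 3)
  invisible(object$by_recording)
}

#' Evaluate an estimated lip-keypoint corpus against hand labels
#'
#' For every frame present in both corpora, computes the hand and estimated
#' lip measures (width, aperture, rounding) in mm and the per-lip modified
#' MSD between hand and estimated lip splines. Frames in which any of the
#' eight lip keypoints falls at or below the confidence cutoff are skipped
#' (the aperture needs the full octet) and counted.
#'
#' @inheritParams run_tongue_eval
#' @param rounding_distance Distance convention for the rounding index
#'   (`"euclidean"` or `"vertical"`).
#' @return Object of class `lip_eval`: `frames` (per-frame measures and
#'   deltas), `by_recording`, `overall` (means of the per-frame columns),
#'   `skipped`.
#' @export
run_lip_eval <- function(hand_dir, est_dir, pcutoff = 0.6, n_samples = 100L,
                         rounding_distance = c("euclidean", "vertical")) {
  rounding_distance <- match.arg(rounding_distance)
  files <- .match_corpora(hand_dir, est_dir)
  rows <- list()
  skipped <- list()
  for (k in seq_along(files$hand)) {
    hrec <- .read_corpus_recording(files$hand[k])
    erec <- .read_corpus_recording(files$est[k])
    hidx <- vapply(hrec$frames, function(f) attr(f, "frame_index"), integer(1))
    eidx <- vapply(erec$frames, function(f) attr(f, "frame_index"), integer(1))
    for (fi in intersect(hidx, eidx)) {
      hand <- to_mm(hrec$frames[[match(fi, hidx)]], hrec$scale)
      est <- to_mm(erec$frames[[match(fi, eidx)]], erec$scale)
      est_f <- filter_by_confidence(est, pcutoff)
      if (!all(lip_keypoints %in% est_f$name) ||
          !all(lip_keypoints %in% hand$name)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          recording_id = hrec$recording_id, frame_index = fi,
          reason = "incomplete lip octet", stringsAsFactors = FALSE
        )
        next
      }
      ev <- evaluate_lips(hand, est_f, n_samples)
      rows[[length(rows) + 1L]] <- data.frame(
        recording_id = hrec$recording_id, frame_index = fi,
        width_hand_mm = lip_width(hand), width_est_mm = lip_width(est_f),
        aperture_hand_mm2 = lip_aperture(hand, n_samples),
        aperture_est_mm2 = lip_aperture(est_f, n_samples),
        rounding_hand = lip_rounding(hand, rounding_distance),
        rounding_est = lip_rounding(est_f, rounding_distance),
        msd_upper_mm = ev$msd_upper_mm, msd_lower_mm = ev$msd_lower_mm,
        width_diff_mm = ev$width_diff, aperture_diff_mm2 = ev$aperture_diff,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) stop("no evaluable frames in the two corpora")
  frames <- do.call(rbind, rows)
  num_cols <- vapply(frames, is.numeric, logical(1))
  num_cols["frame_index"] <- FALSE
  agg <- function(g, id) {
    out <- as.data.frame(lapply(g[num_cols], mean))
    cbind(data.frame(group_id = id, stringsAsFactors = FALSE), out,
      n_frames = nrow(g)
    )
  }
  by_rec <- do.call(rbind, lapply(
    split(frames, frames$recording_id),
    function(g) agg(g, g$recording_id[1L])
  ))
  rownames(by_rec) <- NULL
  structure(
    list(
      frames = frames, by_recording = by_rec,
      overall = agg(frames, "overall"),
      skipped = if (length(skipped)) do.call(rbind, skipped) else
        data.frame(
          recording_id = character(), frame_index = integer(),
          reason = character(), stringsAsFactors = FALSE
        ),
      config = list(
        pcutoff = pcutoff, n_samples = n_samples,
        rounding_distance = rounding_distance
      )
    ),
    class = "lip_eval"
  )
}

#' @export
print.lip_eval <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    paste0(
      "<lip_eval> %d frames, %d recordings (%d skipped)\n",
      "  MSD upper %.3f mm, lower %.3f mm\n",
      "  mean width diff %+.2f mm, mean aperture diff %+.1f mm^2\n"
    ),
    o$n_frames, nrow(x$by_recording), nrow(x$skipped),
    o$msd_upper_mm, o$msd_lower_mm, o$width_diff_mm, o$aperture_diff_mm2
  ))
  invisible(x)
}

#' Correlate EMA sensor trajectories with estimated keypoints
#'
#' Aligns each modality to its own bite plane, resamples the EMA
#' trajectories at the ultrasound frame times (`frame_index / fps`), pairs
#' each sensor with its matching keypoint (TT-tip1, TBl-blade1,
#' TD-dorsum1), and reports per-sensor, per-coordinate Pearson
#' correlations pooled across recordings plus a per-recording table.
#'
#' @param ema Either the path of an EMA table (see [read_ema_table()]) or
#'   the list that function returns.
#' @param kp Either a corpus directory of keypoint CSVs (+ metadata) or a
#'   named list of [recording()] objects keyed by recording id.
#' @param planes List with `ema` and `kp` entries, each a [bite_plane()]
#'   (applied to every recording), or a path to a YAML file of the form
#'   `ema: [[x1,y1],[x2,y2]]`, `kp: [[x1,y1],[x2,y2]]`.
#' @return Object of class `ema_eval`: `pooled` and `per_recording`
#'   correlation tables and `pairs` (the aligned pairs).
#' @export
run_ema_eval <- function(ema, kp, planes) {
  if (is.character(ema)) ema <- read_ema_table(ema)
  if (is.character(kp)) {
    files <- .list_corpus(kp)
    recs <- lapply(files, .read_corpus_recording)
    names(recs) <- vapply(recs, function(r) r$recording_id, character(1))
    kp <- recs
  }
  if (is.character(planes)) {
    pl <- yaml::read_yaml(planes)
    planes <- list(
      ema = bite_plane(unlist(pl$ema[[1]]), unlist(pl$ema[[2]])),
      kp = bite_plane(unlist(pl$kp[[1]]), unlist(pl$kp[[2]]))
    )
  }
  shared <- intersect(names(ema), names(kp))
  if (!length(shared)) stop("no recordings shared between EMA and keypoints")
  pairs <- list()
  for (rid in shared) {
    rec <- kp[[rid]]
    if (is.na(rec$fps)) stop("recording '", rid, "' has no fps metadata")
    scale <- if (is.null(rec$scale)) 1 else rec$scale$mm_per_pixel
    idx <- vapply(rec$frames, function(f) attr(f, "frame_index"), integer(1))
    t_frames <- idx / rec$fps
    for (s in names(ema_sensor_keypoints)) {
      traj <- ema[[rid]][[s]]
      if (is.null(traj)) next
      keep <- t_frames >= min(traj$times) & t_frames <= max(traj$times)
      if (sum(keep) < 3L) {
        stop("no temporal overlap between EMA and keypoints for ", rid)
      }
      kname <- ema_sensor_keypoints[[s]]
      kxy <- t(vapply(rec$frames[keep], function(f) {
        i <- match(kname, f$name)
        c(f$x[i], f$y[i]) * scale
      }, numeric(2)))
      traj_al <- align_to_bite_plane(traj, planes$ema)
      kxy_al <- align_to_bite_plane(kxy, planes$kp)
      exy <- resample_to_frames(traj_al, t_frames[keep])
      pairs[[length(pairs) + 1L]] <- aligned_pair(
        s, t_frames[keep], exy, kxy_al,
        recording_id = rid
      )
    }
  }
  structure(
    list(
      pooled = correlate_sensors(pairs),
      per_recording = correlate_sensors(pairs, per_recording = TRUE),
      pairs = pairs
    ),
    class = "ema_eval"
  )
}

#' @export
print.ema_eval <- function(x, ...) {
  cat(sprintf(
    "<ema_eval> %d aligned pairs over %d recording(s)\n",
    length(x$pairs), length(unique(x$per_recording$recording_id))
  ))
  print.data.frame(x$pooled, digits = 3)
  invisible(x)
}

#' Write an evaluation result as CSV report files
#'
#' Writes `frames.csv` (per-frame results; for tongue evaluations its
#' `msd_mm` and `pct` columns are the MSD-vs-length scatter data),
#' `summary.csv` (per-recording and overall rows) and `skipped.csv`.
#' Every summary number is recomputable from `frames.csv`.
#'
#' @param x A `tongue_eval` or `lip_eval` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    frames = file.path(dir, "frames.csv"),
    summary = file.path(dir, "summary.csv"),
    skipped = file.path(dir, "skipped.csv")
  )
  utils::write.csv(x$frames, paths[["frames"]], row.names = FALSE)
  utils::write.csv(rbind(x$by_recording, x$overall), paths[["summary"]],
    row.names = FALSE
  )
  utils::write.csv(x$skipped, paths[["skipped"]], row.names = FALSE)
  invisible(paths)
}
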
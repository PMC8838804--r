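#' Canonical keypoint names
#'
#' The eleven tongue-surface keypoints in anatomical order (posterior
#' vallecula to anterior tip), the three fixed reference points visible in
#' midsagittal ultrasound, and the eight lip keypoints. The tongue spline is
#' always built through the tongue-surface set in this order.
#'
#' @format Character vectors.
#' @name keypoint_names
NULL

#' @rdname keypoint_names
#' @export
tongue_keypoints <- c(
  "vallecula", "root1", "root2", "back1", "back2",
  "dorsum1", "dorsum2", "blade1", "blade2", "tip1", "tip2"
)

#' @rdname keypoint_names
#' @export
reference_keypoints <- c("hyoid", "mandibleBase", "shortTendon")

#' @rdname keypoint_names
#' @export
lip_keypoints <- LETTERS[1:8]

#' Construct a single frame of named keypoints
#'
#' A frame is a data frame with one row per keypoint and columns `name`,
#' `x`, `y` (image convention: origin top-left, y increases downward) and
#' `confidence` in \[0, 1\]. Missing coordinates are allowed (NA) and should
#' carry confidence 0 so any positive cutoff removes them.
#'
#' @param name Character vector of unique keypoint labels.
#' @param x,y Numeric coordinates (pixels or mm; the frame itself is
#'   unit-agnostic).
#' @param confidence Numeric in \[0, 1\], recycled if length 1.
#' @param frame_index Non-negative integer frame number (0-based).
#' @param time_s Optional time in seconds (typically `frame_index / fps`).
#' @return An object of class `frame_keypoints` (a data frame).
#' @export
frame_keypoints <- function(name, x, y, confidence = 1,
                            frame_index = 0L, time_s = NA_real_) {
  name <- as.character(name)
  n <- length(name)
  if (length(confidence) == 1L) confidence <- rep(confidence, n)
  if (length(x) != n || length(y) != n || length(confidence) != n) {
    stop("name, x, y and confidence must have equal lengths")
  }
  if (anyDuplicated(name)) {
    stop("keypoint names must be unique within a frame")
  }
  confidence <- as.numeric(confidence)
  if (any(!is.na(confidence) & (confidence < 0 | confidence > 1))) {
    stop("confidence must lie in [0, 1]")
  }
  df <- data.frame(
    name = name, x = as.numeric(x), y = as.numeric(y),
    confidence = confidence, stringsAsFactors = FALSE
  )
  structure(df,
    frame_index = as.integer(frame_index), time_s = as.numeric(time_s),
    class = c("frame_keypoints", "data.frame")
  )
}

#' @export
print.frame_keypoints <- function(x, ...) {
  cat(sprintf(
    "<frame_keypoints> frame %d, %d keypoints\n",
    attr(x, "frame_index"), nrow(x)
  ))
  print.data.frame(x, ...)
  invisible(x)
}

#' Per-recording pixel-to-mm scale
#'
#' The pixel-to-mm scale is recording-specific (probe depth and letterboxing
#' differ between recordings), so it is carried as explicit metadata rather
#' than inferred. Either give `mm_per_pixel` directly or both
#' `field_height_mm` and `image_height_px`, in which case
#' `mm_per_pixel = field_height_mm / image_height_px`.
#'
#' @param mm_per_pixel Millimetres per pixel (> 0).
#' @param field_height_mm Imaged field height in mm.
#' @param image_height_px Image height in pixels.
#' @return An object of class `scale_info`.
#' @export
scale_info <- function(mm_per_pixel = NULL, field_height_mm = NULL,
                       image_height_px = NULL) {
  if (is.null(mm_per_pixel)) {
    if (is.null(field_height_mm) || is.null(image_height_px)) {
      stop("give mm_per_pixel, or both field_height_mm and image_height_px")
    }
    mm_per_pixel <- field_height_mm / image_height_px
  }
  if (!is.finite(mm_per_pixel) || mm_per_pixel <= 0) {
    stop("mm_per_pixel must be a positive finite number")
  }
  structure(
    list(
      mm_per_pixel = mm_per_pixel,
      field_height_mm = if (is.null(field_height_mm)) NA_real_ else field_height_mm,
      image_height_px = if (is.null(image_height_px)) NA_real_ else image_height_px
    ),
    class = "scale_info"
  )
}

#' Construct a recording (an ordered sequence of keypoint frames)
#'
#' @param frames List of [frame_keypoints()] objects with strictly
#'   increasing frame indices.
#' @param recording_id Identifier (typically the speaker/recording name).
#' @param fps Frame rate in frames per second (used to derive frame times).
#' @param scale Optional [scale_info()].
#' @return An object of class `recording`.
#' @export
recording <- function(frames, recording_id = "recording", fps = NA_real_,
                      scale = NULL) {
  if (!length(frames)) stop("a recording needs at least one frame")
  idx <- vapply(frames, function(f) attr(f, "frame_index"), integer(1))
  if (any(diff(idx) <= 0L)) stop("frame indices must be strictly increasing")
  structure(
    list(
      recording_id = recording_id, fps = as.numeric(fps),
      frames = frames, scale = scale
    ),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> '%s': %d frames, fps = %s, scale = %s mm/px\n",
    x$recording_id, length(x$frames),
    format(x$fps), if (is.null(x$scale)) "?" else format(x$scale$mm_per_pixel)
  ))
  invisible(x)
}

# Format a numeric so that read.csv round-trips it bit-exactly.
.fmt_num <- function(v) {
  out <- vapply(v, function(z) {
    if (is.na(z)) "" else sprintf("%.17g", z)
  }, character(1))
  out
}

#' Read a DeepLabCut-style keypoint CSV
#'
#' Parses the three-header-row dialect emitted by markerless pose-estimation
#' tools: row 1 `scorer`, row 2 `bodyparts` (each name repeated three times),
#' row 3 `coords` (`x`, `y`, `likelihood` per bodypart), then one data row
#' per frame whose first column is the frame index. The `likelihood` column
#' is mapped to keypoint confidence. Empty cells become missing coordinates
#' with confidence 0, so any positive confidence cutoff removes them.
#'
#' @param path Path to the CSV file.
#' @param recording_id Identifier; defaults to the file name without
#'   extension.
#' @param fps Frame rate (optional; used to fill per-frame times).
#' @param scale Optional [scale_info()] attached to the recording.
#' @return A [recording()].
#' @export
read_dlc_csv <- function(path, recording_id = sub("\\.csv$", "", basename(path)),
                         fps = NA_real_, scale = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 4L) {
    stop("malformed header: expected 3 header rows plus at least 1 data row")
  }
  hdr <- strsplit(lines[1:3], ",", fixed = TRUE)
  if (tolower(hdr[[1]][1]) != "scorer" ||
      tolower(hdr[[2]][1]) != "bodyparts" ||
      tolower(hdr[[3]][1]) != "coords") {
    stop(
      "malformed header: first column of the 3 header rows must be ",
      "'scorer', 'bodyparts', 'coords'"
    )
  }
  bodyparts <- hdr[[2]][-1]
  coords <- hdr[[3]][-1]
  if (length(bodyparts) != length(coords) || length(bodyparts) %% 3L != 0L) {
    stop("malformed header: bodypart columns must come in x/y/likelihood triplets")
  }
  nbp <- length(bodyparts) %/% 3L
  for (k in seq_len(nbp)) {
    cols <- (k - 1L) * 3L + 1:3
    if (length(unique(bodyparts[cols])) != 1L) {
      stop(sprintf(
        "malformed header: columns %d-%d do not repeat a single bodypart name",
        cols[1] + 1L, cols[3] + 1L
      ))
    }
    if (!identical(tolower(coords[cols]), c("x", "y", "likelihood"))) {
      stop(sprintf(
        "malformed header: coords row at column %d must read x,y,likelihood",
        cols[1] + 1L
      ))
    }
  }
  names_bp <- bodyparts[seq(1L, by = 3L, length.out = nbp)]

  raw <- utils::read.csv(
    text = paste(lines[-(1:3)], collapse = "\n"),
    header = FALSE, colClasses = "character", stringsAsFactors = FALSE
  )
  if (ncol(raw) != length(bodyparts) + 1L) {
    stop("malformed data: row width does not match header width")
  }
  num <- matrix(NA_real_, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw))) {
    cell <- trimws(raw[[j]])
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & nzchar(cell) & is.na(val))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric cell '%s' at data row %d, column %d",
        cell[bad[1]], bad[1], j
      ))
    }
    num[, j] <- val
  }

  frames <- vector("list", nrow(num))
  for (i in seq_len(nrow(num))) {
    fi <- num[i, 1]
    if (is.na(fi)) stop(sprintf("missing frame index at data row %d", i))
    xs <- num[i, 1L + (seq_len(nbp) - 1L) * 3L + 1L]
    ys <- num[i, 1L + (seq_len(nbp) - 1L) * 3L + 2L]
    cf <- num[i, 1L + (seq_len(nbp) - 1L) * 3L + 3L]
    cf[is.na(cf)] <- 0
    cf[is.na(xs) | is.na(ys)] <- 0
    frames[[i]] <- frame_keypoints(
      names_bp, xs, ys, cf,
      frame_index = as.integer(fi),
      time_s = if (is.na(fps)) NA_real_ else fi / fps
    )
  }
  recording(frames, recording_id = recording_id, fps = fps, scale = scale)
}

#' Write a recording as a DeepLabCut-style keypoint CSV
#'
#' Emits the same three-header-row dialect accepted by [read_dlc_csv()].
#' Numeric values are written with full precision so a read/write round trip
#' reproduces them exactly. Keypoints absent from a frame are written as
#' empty cells (missing coordinates, confidence 0 on re-read).
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @param scorer Value for the `scorer` header row.
#' @return Invisibly, `path`.
#' @export
write_dlc_csv <- function(rec, path, scorer = "articulometry") {
  if (!inherits(rec, "recording")) stop("rec must be a recording")
  if (!length(rec$frames)) stop("cannot write an empty recording")
  nm <- unique(unlist(lapply(rec$frames, function(f) f$name)))
  hdr1 <- paste(c("scorer", rep(scorer, 3L * length(nm))), collapse = ",")
  hdr2 <- paste(c("bodyparts", rep(nm, each = 3L)), collapse = ",")
  hdr3 <- paste(c("coords", rep(c("x", "y", "likelihood"), length(nm))),
    collapse = ","
  )
  rows <- vapply(rec$frames, function(f) {
    m <- match(nm, f$name)
    cells <- character(3L * length(nm))
    cells[seq(1L, by = 3L, length.out = length(nm))] <- .fmt_num(f$x[m])
    cells[seq(2L, by = 3L, length.out = length(nm))] <- .fmt_num(f$y[m])
    conf <- f$confidence[m]
    conf[is.na(m)] <- NA_real_
    cells[seq(3L, by = 3L, length.out = length(nm))] <- .fmt_num(conf)
    paste(c(sprintf("%d", attr(f, "frame_index")), cells), collapse = ",")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr1, hdr2, hdr3, rows), con)
  invisible(path)
}

#' Drop keypoints at or below a confidence cutoff
#'
#' Retains exactly the keypoints with `confidence > pcutoff` (strict
#' inequality: a point at exactly the cutoff is excluded), preserving order.
#' The conventional cutoff for estimated keypoints is 0.6.
#'
#' @param frame A [frame_keypoints()].
#' @param pcutoff Confidence cutoff in \[0, 1\].
#' @return A filtered `frame_keypoints` (possibly with zero rows).
#' @export
filter_by_confidence <- function(frame, pcutoff = 0.6) {
  if (!is.numeric(pcutoff) || pcutoff < 0 || pcutoff > 1) {
    stop("pcutoff must lie in [0, 1]")
  }
  keep <- !is.na(frame$confidence) & frame$confidence > pcutoff
  out <- frame[keep, , drop = FALSE]
  structure(out,
    frame_index = attr(frame, "frame_index"),
    time_s = attr(frame, "time_s"),
    class = c("frame_keypoints", "data.frame")
  )
}

#' Convert frame coordinates from pixels to millimetres
#'
#' Multiplies both coordinates by the recording's mm-per-pixel factor;
#' confidences are unchanged. All shape metrics downstream are computed in
#' mm, with the scale taken from per-recording metadata.
#'
#' @param frame A [frame_keypoints()] in pixel units.
#' @param scale A [scale_info()] or a positive number (mm per pixel).
#' @return The frame with coordinates in mm.
#' @export
to_mm <- function(frame, scale) {
  s <- if (inherits(scale, "scale_info")) scale$mm_per_pixel else scale
  if (!is.numeric(s) || !is.finite(s) || s <= 0) {
    stop("scale must be a positive mm-per-pixel factor")
  }
  frame$x <- frame$x * s
  frame$y <- frame$y * s
  frame
}

#' Read and write per-recording metadata
#'
#' Metadata is a small YAML file with fields `recording_id`, `fps`,
#' `field_height_mm` and `image_height_px`; the mm-per-pixel scale is derived
#' as `field_height_mm / image_height_px`.
#'
#' @param path Path to the YAML file.
#' @return For `read_recording_meta`, a list with the fields above plus a
#'   `scale` ([scale_info()]) entry.
#' @export
read_recording_meta <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  meta <- yaml::read_yaml(path)
  req <- c("recording_id", "fps", "field_height_mm", "image_height_px")
  miss <- setdiff(req, names(meta))
  if (length(miss)) {
    stop("metadata missing fields: ", paste(miss, collapse = ", "))
  }
  meta$scale <- scale_info(
    field_height_mm = meta$field_height_mm,
    image_height_px = meta$image_height_px
  )
  meta
}

#' @rdname read_recording_meta
#' @param meta List with fields `recording_id`, `fps`, `field_height_mm`,
#'   `image_height_px`.
#' @export
write_recording_meta <- function(meta, path) {
  req <- c("recording_id", "fps", "field_height_mm", "image_height_px")
  miss <- setdiff(req, names(meta))
  if (length(miss)) {
    stop("metadata missing fields: ", paste(miss, collapse = ", "))
  }
  yaml::write_yaml(meta[req], path)
  invisible(path)
}
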
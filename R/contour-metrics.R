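# Curve-agreement statistics: the modified mean sum of distances (MSD) with
# its endpoint rule, the plain symmetric MSD, the separate spline length
# difference, confidence-gated keypoint RMSE, per-group aggregation and the
# two-tailed t-tests used for result tables.

# For each row of A, distance to the nearest row of B and its index.
.nearest_all <- function(A, B) {
  dx <- outer(A[, 1L], B[, 1L], "-")
  dy <- outer(A[, 2L], B[, 2L], "-")
  D2 <- dx * dx + dy * dy
  j <- max.col(-D2, ties.method = "first")
  list(d = sqrt(D2[cbind(seq_len(nrow(A)), j)]), j = j)
}

# Distances from source curve S to target curve T. With collapse = TRUE,
# all source points whose nearest neighbour is an endpoint of T are
# collapsed, per endpoint, to the single shortest such distance. This is
# what makes the modified MSD insensitive to one curve overhanging the
# other: the overhang's many distances to the shared endpoint count once.
.directed_distances <- function(S, T, collapse = TRUE) {
  nn <- .nearest_all(S, T)
  if (!collapse) return(nn$d)
  nT <- nrow(T)
  interior <- nn$j != 1L & nn$j != nT
  out <- nn$d[interior]
  for (e in unique(c(1L, nT))) {
    de <- nn$d[nn$j == e]
    if (length(de)) out <- c(out, min(de))
  }
  out
}

.msd_impl <- function(curveA, curveB, collapse) {
  A <- .as_xy(curveA)
  B <- .as_xy(curveB)
  if (nrow(A) < 2L || nrow(B) < 2L) {
    stop("both curves need at least 2 samples")
  }
  dab <- .directed_distances(A, B, collapse)
  dba <- .directed_distances(B, A, collapse)
  structure(
    list(
      msd_mm = (sum(dab) + sum(dba)) / (length(dab) + length(dba)),
      n_distances = length(dab) + length(dba),
      per_direction = list(ab = dab, ba = dba)
    ),
    class = "msd_result"
  )
}

#' Mean sum of distances between two sampled curves (modified form)
#'
#' Symmetric nearest-point distance mean with an endpoint rule: in each
#' direction, all distances whose nearest neighbour on the target curve is
#' one of that curve's endpoints are collapsed, per endpoint, to the single
#' shortest such distance, and the denominator counts only retained
#' distances. Consequently the statistic is unaffected by the relative
#' lengths of the curves: if one curve is a sub-curve lying exactly on the
#' other, the result is (numerically) zero, and curve length disagreement
#' is reported separately by [length_difference()].
#'
#' Both curves should be resampled to the same density (the package default
#' is 100 samples, see [interpolate_spline()]) before calling.
#'
#' @param curveA,curveB Curve matrices with >= 2 samples each.
#' @return An object of class `msd_result`: list with `msd_mm` (the
#'   statistic), `n_distances` (retained distance count) and
#'   `per_direction` (retained distances A to B and B to A).
#' @seealso [msd_standard()] for the unmodified baseline.
#' @export
msd_modified <- function(curveA, curveB) .msd_impl(curveA, curveB, TRUE)

#' Mean sum of distances between two sampled curves (standard form)
#'
#' The plain symmetric nearest-point distance mean without the endpoint
#' rule: every sample of each curve contributes its distance to the nearest
#' sample of the other curve, and the sum is divided by the total number of
#' distances. Unlike [msd_modified()], an overhanging portion of one curve
#' inflates the score even when the overlapping portions match exactly.
#'
#' @inheritParams msd_modified
#' @return An `msd_result` (see [msd_modified()]).
#' @export
msd_standard <- function(curveA, curveB) .msd_impl(curveA, curveB, FALSE)

#' @export
print.msd_result <- function(x, ...) {
  cat(sprintf(
    "MSD = %.4f mm (over %d retained distances)\n",
    x$msd_mm, x$n_distances
  ))
  invisible(x)
}

#' Signed spline length difference
#'
#' Difference of arc lengths between the estimated and hand-labelled
#' curves, reported in mm and as a percentage of the hand-labelled length.
#' The sign convention is estimated minus hand-labelled, so an estimator
#' that draws contours longer than the hand labels scores positive.
#'
#' @param hand Hand-labelled curve matrix.
#' @param est Estimated curve matrix.
#' @return List of class `length_diff` with `diff_mm` (signed mm) and
#'   `pct` (signed percent of the hand-labelled length).
#' @export
length_difference <- function(hand, est) {
  lh <- arc_length(hand)
  le <- arc_length(est)
  if (lh <= 0) stop("hand-labelled curve has zero length")
  structure(
    list(diff_mm = le - lh, pct = 100 * (le - lh) / lh),
    class = "length_diff"
  )
}

#' @export
print.length_diff <- function(x, ...) {
  cat(sprintf("length difference: %+.3f mm (%+.2f%%)\n", x$diff_mm, x$pct))
  invisible(x)
}

#' Confidence-gated RMSE between matched keypoints
#'
#' Root mean square Euclidean distance between hand-labelled and estimated
#' keypoints, over the keypoints present (with finite coordinates) in both
#' frames whose estimated confidence exceeds `pcutoff`. Keypoints the
#' estimator is unsure about (e.g. a tongue tip obscured by the mandible
#' shadow) are thereby ignored.
#'
#' @param hand,est [frame_keypoints()] sharing keypoint names. Units are
#'   the caller's (pixels by convention for this measure).
#' @param pcutoff Confidence cutoff applied to `est` (default 0.6).
#' @return RMSE in the input units, or `NA` if no keypoint survives the
#'   cutoff.
#' @export
rmse_keypoints <- function(hand, est, pcutoff = 0.6) {
  shared <- intersect(hand$name, est$name)
  if (!length(shared)) stop("no shared keypoint names between frames")
  hi <- match(shared, hand$name)
  ei <- match(shared, est$name)
  ok <- is.finite(hand$x[hi]) & is.finite(hand$y[hi]) &
    is.finite(est$x[ei]) & is.finite(est$y[ei]) &
    !is.na(est$confidence[ei]) & est$confidence[ei] > pcutoff
  if (!any(ok)) return(NA_real_)
  d2 <- (hand$x[hi] - est$x[ei])[ok]^2 + (hand$y[hi] - est$y[ei])[ok]^2
  sqrt(mean(d2))
}

#' Aggregate per-frame contour evaluations for a group
#'
#' Mean, sample standard deviation (n - 1 denominator) and median of the
#' per-frame MSD and percent length difference, with frames weighted
#' equally. A single-frame group reports sd = 0 with a warning rather than
#' failing, so sparse groups still tabulate.
#'
#' @param frames Data frame of per-frame results with numeric columns
#'   `msd_mm` and `pct` (as produced by [run_tongue_eval()]).
#' @param group_id Label for the group (speaker, method, ...).
#' @return One-row data frame of class `eval_summary`.
#' @export
summarize_frames <- function(frames, group_id = "all") {
  if (!nrow(frames)) stop("no frames to summarize")
  sd1 <- function(v) {
    if (length(v) < 2L) {
      warning("single observation: reporting sd = 0")
      return(0)
    }
    stats::sd(v)
  }
  out <- data.frame(
    group_id = group_id,
    msd_mean = mean(frames$msd_mm),
    msd_sd = sd1(frames$msd_mm),
    msd_median = stats::median(frames$msd_mm),
    pct_mean = mean(frames$pct),
    pct_sd = sd1(frames$pct),
    pct_median = stats::median(frames$pct),
    n_frames = nrow(frames),
    stringsAsFactors = FALSE
  )
  class(out) <- c("eval_summary", "data.frame")
  out
}

#' Two-tailed t-test between two MSD distributions
#'
#' Compares per-frame statistic distributions between two methods (or a
#' method and the inter-labeller reference) with a two-tailed t-test,
#' either Student's (equal variance) or Welch's with Satterthwaite degrees
#' of freedom (unequal variance).
#'
#' @param a,b Numeric samples (each of length >= 2).
#' @param variant `"unequal"` (Welch, the default) or `"equal"` (Student).
#' @return List of class `ttest_result` with `t`, `df`, `p` and `variant`.
#' @export
compare_distributions <- function(a, b, variant = c("unequal", "equal")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 observations")
  }
  ht <- stats::t.test(a, b,
    var.equal = (variant == "equal"),
    alternative = "two.sided"
  )
  structure(
    list(
      t = unname(ht$statistic), df = unname(ht$parameter),
      p = ht$p.value, variant = variant
    ),
    class = "ttest_result"
  )
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf(
    "two-tailed t-test (%s variance): t = %.3f, df = %.2f, p = %.4g\n",
    x$variant, x$t, x$df, x$p
  ))
  invisible(x)
}
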
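# articulometry

Keypoint-based measurement of speech articulator kinematics.

Speech scientists increasingly extract tongue, lip, jaw and hyoid movement
from midsagittal ultrasound and front-facing camera video using markerless
pose estimation: a trained network emits, per video frame, a set of named
anatomical keypoints with confidence scores (the familiar DeepLabCut CSV
layout). Turning those keypoints into defensible kinematic measurements —
and knowing how much to trust them against hand labels or against
electromagnetic articulography (EMA) — requires a specific measurement
stack. This package implements that stack for R users: phoneticians,
clinical speech researchers and anyone evaluating a contour- or
keypoint-estimation method on articulatory image data.

## What it computes

**Modified mean sum of distances (MSD).** Two contours are each resampled
to *n* = 100 points on an interpolating cubic spline through their control
points (for the tongue, 11 keypoints from vallecula to tip2). The standard
MSD is the symmetric mean of nearest-point distances:

    MSD(A, B) = ( Σ_a min_b ‖a − b‖ + Σ_b min_a ‖a − b‖ ) / (N_A + N_B)

Its weakness is that a perfectly placed but shorter contour scores the same
as an equal-length contour that misses: the overhang's distances pile onto
the nearer curve's endpoint. The modified form applies an *endpoint rule*:
in each direction, all distances whose nearest neighbour is an endpoint of
the target curve are collapsed, per endpoint, to the single shortest such
distance, and the denominator counts only retained distances. An exact
sub-curve of a contour then scores 0, and length disagreement is reported
separately as a signed spline length difference (estimate − hand label, in
mm and in percent).

**Keypoint RMSE.** Root mean square Euclidean error over keypoints whose
estimated confidence exceeds a cutoff (0.6 by convention), so low-confidence
points — e.g. a tongue tip lost in the mandible shadow — are ignored.

**Lip measures.** From the eight lip keypoints (A, B commissures; C, D
upper/lower midline; E–H midway points) the package builds upper and lower
lip splines sharing the commissures, and computes lip width ‖A − B‖,
aperture area (shoelace area between the splines, mm²) and the rounding
index

    ( ‖C − D‖ − 0.5 (‖E − F‖ + ‖G − H‖) ) / ‖A − B‖ .

**EMA comparison.** EMA sensor trajectories (TT, TBl, TD) and the matching
estimated keypoints (tip1, blade1, dorsum1) are each rotated so the
recorded bite plane forms the x-axis, the EMA is linearly resampled at the
ultrasound frame times, and agreement is reported as per-sensor,
per-coordinate Pearson correlations, pooled across recordings.

**Synthetic data.** Generators produce tongue-like truth contours with the
11-keypoint scheme (blade/tip spacing half that of the body), lip frames
honouring the A–H placement rules, labeller-style noise (normal/tangential
jitter, low-confidence dropout, per-frame perpendicular offsets), paired
EMA/keypoint sessions sharing latent motion, and whole on-disk corpora —
so every stage of the pipeline is testable without any recordings.

## Worked example

Generate a 5-speaker, 20-frame synthetic corpus whose "estimates" carry a
per-frame perpendicular offset d ~ N(0, 1.25 mm²), then evaluate it:

```r
library(articulometry)
corpus <- file.path(tempdir(), "demo")
gen_fixture_corpus(corpus, n_recordings = 5, frames_per_recording = 20,
                   seed = 42)
ev <- run_tongue_eval(file.path(corpus, "hand"), file.path(corpus, "est"))
ev
#> <tongue_eval> 100 frames, 5 recordings (0 skipped)
#>   MSD (modified): mean 1.124, sd 0.901, median 0.940 mm
#>   %length diff: mean -0.04, sd 2.88, median +0.27
```

The mean MSD estimates E|d| = 1.25·√(2/π) ≈ 1.0 mm (a 100-frame corpus
carries a Monte-Carlo error of about ±0.08 mm, hence 1.124 here); the
length difference is centred on zero because a perpendicular offset barely
changes arc length. Per-speaker rows live in `ev$by_recording`, per-frame
values (the MSD-vs-%length scatter data) in `ev$frames`, and
`write_eval_report(ev, dir)` writes them as CSV.

Lip measures on a single frame:

```r
f <- lip_frame(rbind(A = c(0, 0), B = c(40, 0), C = c(20, 10),
                     D = c(20, -10), E = c(10, 7), F = c(10, -7),
                     G = c(30, 7), H = c(30, -7)))
lip_width(f)     # 40 mm
lip_aperture(f)  # 506.5 mm^2
lip_rounding(f)  # (20 - 14) / 40 = 0.15
```

A command-line wrapper with `evaluate-tongue`, `evaluate-lips`,
`compare-ema` and `simulate` subcommands is installed at
`inst/cli/articulometry.R`.

## Corpus layout

A corpus directory holds one DeepLabCut-style CSV per recording (3 header
rows: scorer / bodyparts / coords, with x, y, likelihood per keypoint) and
a sibling `<recording>.yaml` with `recording_id`, `fps`,
`field_height_mm` and `image_height_px`; the mm-per-pixel scale is
`field_height_mm / image_height_px`, carried per recording. Hand and
estimate corpora are matched by file name and frame index.

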
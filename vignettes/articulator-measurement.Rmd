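---
title: "Measuring speech articulator keypoints: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring speech articulator keypoints: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(articulometry)
```

This vignette is the package's account of its own methods: what the
statistics assume, why the defaults are what they are, and what the
synthetic generators do and do not emulate. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The measurement problem

Markerless pose estimation gives, per video frame, a set of named
anatomical keypoints with confidence scores. For midsagittal ultrasound of
the tongue the keypoints are eleven surface points in anatomical order
(`vallecula` … `tip2`) plus three fixed references (hyoid, mandible base,
short tendon — the genioglossus insertion, useful because it is
probe-rotation independent). For lips they are the commissures A and B,
midline points C and D, and midway points E–H. Everything downstream is a
question of comparing geometry: estimated contour vs hand-labelled
contour, estimated keypoint vs hand-labelled keypoint, or estimated
keypoint trajectory vs a physical EMA sensor.

Coordinates keep the image convention (origin top-left, y downward)
throughout. All metrics are distance-based, so the convention never
affects a result, but it must be uniform; the package never flips axes.
Pixel coordinates are converted to mm with a per-recording scale
(`field_height_mm / image_height_px`), carried as explicit metadata
because probe depth and letterboxing differ between recordings and the
scale cannot be inferred from a keypoint file. (How any particular
acquisition package derives its scale for letterboxed video is outside
this package's knowledge — the metadata file makes it explicit instead.)

## Contours from keypoints

Control points are interpolated with a **natural cubic spline under
chord-length parameterization**, evaluated per coordinate, and sampled at
`n = 100` equally spaced parameter values. Interpolation (rather than
smoothing) is the right family here because hand labels and estimates are
both intended to lie *on* the tongue surface; a smoothing fit would move
the comparison away from the labelled points by an amount chosen by a
tuning constant that the data cannot justify. Chord-length
parameterization with natural end conditions is a documented assumption:
the end conditions matter only near the contour ends, where the endpoint
rule below already dominates behaviour. The tests verify that an
11-control-point arc of a 50 mm circle is reproduced to better than
0.5 mm everywhere.

## The modified MSD and its endpoint rule

The standard mean sum of distances between sampled curves A and B is the
symmetric mean of sample-to-nearest-sample distances. It confounds two
different failures: mismatch of overlapping shape, and difference in
extent. The modified form separates them. In each direction, every source
sample whose nearest neighbour on the target curve is one of the target's
*endpoints* belongs to that endpoint's group; each group is collapsed to
its single shortest distance, and the denominator counts only retained
distances.

The wording "only one distance to an endpoint is kept" admits more than
one reading. The implemented reading — per direction and per target-curve
endpoint, keep the minimum over that endpoint's group — is the unique one
with the property the statistic exists for: a contiguous sub-curve lying
exactly on a longer curve scores zero (the overhang's samples all match
the shared endpoint; their group collapses to the one zero-length
distance), while for curves of equal extent no collapse occurs and the
modified form reduces to the standard one. Both behaviours are asserted in
the tests, along with agreement with an independently coded brute-force
implementation on random curve pairs.

Curve extent is reported separately as the **spline length difference**,
estimate − hand label (mm, and percent of the hand-labelled length). The
sign is chosen so that an estimator drawing contours longer than the
labeller scores positive; published evaluation tables in this field use
that orientation even where the accompanying prose writes the subtraction
the other way around.

Numerical notes:

* Nearest distances are **sample-to-sample**, not point-to-segment. At
  100 samples the quantization error is bounded by half the inter-sample
  spacing (about 0.5 mm on a 100 mm contour) and shared by both curves;
  tests that need a sharper reference evaluate the same pair at 10× the
  density. Nearest-neighbour ties break to the lowest sample index.
* `msd_standard ≥ msd_modified` holds whenever the endpoint-matched
  distances are, per group, no smaller than the retained mean — which is
  the case in estimator-vs-label geometry, where endpoint groups are
  overhangs. It is not an algebraic theorem for arbitrary curve pairs; the
  tests assert it on perturbation/truncation ensembles, not adversarial
  ones.
* Identical 100-sample curves retain exactly 200 distances (98 interior
  plus 2 collapsed per direction): the count, not just the mean, is
  checked.

## Keypoint RMSE and confidence gating

RMSE is computed over keypoints present in both frames whose *estimated*
confidence is strictly greater than the cutoff (default 0.6); a point at
exactly the cutoff is excluded, and a frame where nothing survives yields
`NA` rather than an error. Missing CSV cells are read as missing
coordinates with confidence 0, so any positive cutoff removes them. RMSE
and MSD answer different questions — a set of keypoints can hug the
contour perfectly (low MSD) while sliding along it (high RMSE) — which is
why both are reported.

## Lip measures

The upper lip spline passes through A, E, C, G, B and the lower through
A, F, D, H, B; both share the commissures as endpoints. Aperture is the
absolute shoelace area of the polygon formed by the upper samples and the
reversed interior lower samples; if the two splines cross, the absolute
net area is reported with a warning rather than failing mid-corpus. The
rounding index `(‖C−D‖ − 0.5(‖E−F‖ + ‖G−H‖))/‖A−B‖` reads the point
differences as Euclidean distances; a `distance = "vertical"` switch is
provided because the vertical-only reading is also defensible, and the
two differ only when the midline is horizontally offset (asymmetric
philtrum). Aperture and width differences are reported as estimate − hand,
so an estimator that marks the visible lip boundary (a smaller mouth
area than the mucosal labelling convention) shows a negative aperture
difference. Homogeneity under uniform scaling (area ∝ s², width ∝ s,
rounding ∝ s⁰) and invariance under rigid motion are part of the test
suite.

## EMA vs keypoints

Both modalities are rotated so the recorded bite plane forms the x-axis —
rotation about the plane's first point plus a vertical shift, so every
point on the trace lands on y = 0. A pure rotation would leave the trace
at its original height; the added shift makes the shared frame concrete
while remaining a rigid motion, so correlations are unchanged. The EMA
channel (high rate) is linearly resampled at the ultrasound frame times —
not vice versa — because EMA sampling is far above articulatory bandwidth
and interpolation error is second order in the sample interval (tested
against an analytic sinusoid). Correlations are Pearson, per sensor and
coordinate, pooled by concatenating frames across recordings; a
per-recording table is emitted for diagnostics. No amplitude normalization
is applied (Pearson is scale-invariant) and no temporal lag search is
performed: clock alignment is assumed, and any residual lag surfaces as
reduced correlation.

## What the synthetic generators emulate

* **Tongue contours** are a circular fan arc (default radius 50 mm,
  span 2.36 rad about a virtual probe origin — a contour length of about
  118 mm, plausible for an adult midsagittal field of view) plus Gaussian
  bumps at root/dorsum/blade positions with seeded random amplitudes. The
  eleven keypoints sit exactly on the sampled truth curve at arc-length
  fractions giving blade/tip spacing half the body spacing. The shape
  family is synthetic, chosen as the simplest convex-up family with
  controllable gestures; it is not an anatomical model, carries no
  imaging artefacts (shadows, speckle, epiglottis reflections), and its
  labeller noise is stationary across the contour, which real labellers'
  is not. Passing tests therefore demonstrate correctness of the
  *measurement pipeline*, not performance of any estimator on real images.
* **Labeller/estimator noise** has two forms. `perturb_keypoints()`
  applies i.i.d. normal jitter decomposed perpendicular/tangential to the
  local contour, plus low-confidence dropout. Separately,
  `offset_curve_normal()` shifts a whole contour by one signed distance
  along its normals. The *jitter-recovery* conditions use the latter:
  for a per-frame constant perpendicular offset d ~ N(0, σ²), the modified
  MSD equals |d| exactly (each sample's displaced twin is its nearest
  neighbour), so the corpus mean estimates E|d| = σ√(2/π) with no
  interpolation bias. I.i.d. per-keypoint jitter does not have this
  property — the 11-knot spline smooths between displaced knots and the
  recovered mean falls below the half-normal value — so it is the wrong
  construction for calibrating the metric, though the right one for
  stress-testing confidence gating and frame skipping.
* **Noise calibration.** The corpus default σ = 1.25 mm is a calibration
  choice, not a measured value: it places the synthetic corpus mean
  modified MSD near 1 mm (1.25·√(2/π) ≈ 0.997), the magnitude of
  inter-labeller disagreement reported for this kind of data. No
  quantitative model of real labeller disagreement beyond that aggregate
  magnitude is claimed.
* **EMA sessions** share a sum-of-sinusoids latent motion (default
  frequencies 0.9/2.1/3.4 Hz, amplitudes 5/2.5/1.2 mm — articulatory
  bandwidth, latent variance Σa²/2 per coordinate) observed at 250 Hz
  (EMA) and 81.25 Hz (frames) with independent white noise. For an
  attenuation target r, the keypoint noise is σ² = V(1/r² − 1); measured
  correlations match this within Monte-Carlo error at 2000 frames. The
  "decoupled-x" mode drives the keypoint x-coordinate from an independent
  latent at incommensurate frequencies (scaled by (1+√2)/2), emulating the
  empirical pattern that vertical sensor motion is tracked well and
  horizontal motion poorly; sharing frequencies with independent phases
  would *not* decorrelate, which is why the frequencies are scaled.
* **Determinism.** Every generator takes an explicit seed and restores the
  ambient RNG state afterwards; a corpus tree is byte-identical across
  regenerations under the same seed. `seed = NULL` draws from the ambient
  stream so corpus-level generation consumes one seeded stream.

## Problem sizes and runtime choices

The deepest tests run a 25-recording × 40-frame tongue corpus
(1000 frames, matching a realistic multi-speaker test set), a 10 × 40 lip
corpus, 2000-frame EMA sessions, 100-pair brute-force MSD comparisons and
a 20 000-resample permutation check of the t-test — sizes chosen so the
full suite completes in well under a minute while keeping Monte-Carlo
error far inside the asserted tolerances (the 1000-frame corpus estimates
the jitter scale with a standard error of about 2.4%, against a 5%
assertion).

## Known limitations

* Sample-to-sample nearest distances quantize at half the inter-sample
  spacing; contours much shorter than ~20 mm should be evaluated at higher
  `n_samples`.
* The endpoint rule makes the MSD insensitive to extent, which is the
  design intent — but it also means a wildly short estimate can score
  well on MSD alone. Always read the length difference alongside it.
* The aperture of self-intersecting lip configurations is an absolute net
  area, flagged by a warning, not a geometric repair.
* No head-movement or probe-motion compensation, no clock-lag estimation,
  and no parsing of proprietary EMA hardware formats: inputs are plain
  tables in a shared time base.
* The synthetic shape families support verification and calibration only;
  none of the numbers they produce are claims about any estimator's
  accuracy on real recordings.
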
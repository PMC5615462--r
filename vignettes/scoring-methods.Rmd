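---
title: "Scoring a laser-pointer tracing test: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring a laser-pointer tracing test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lasertrace)
```

## The test and its outcome variables

A participant holds a laser pointer and traces, at self-chosen speed, the
thin black center line of a zig-zag pattern printed on an A3 board one metre
away, while a fixed camera records the board. Each trial is scored by two
variables:

* **Acuity** — the percentage of trial time during which the laser dot
  touches the black line. This is the primary movement-sense outcome.
* **Speed** — the average movement speed of the dot in mm/s over the trial.

`lasertrace` implements the full scoring chain for such recordings: target
geometry, pixel-to-millimetre calibration, per-frame dot detection, trial
segmentation, outcome computation, and the reliability statistics used to
evaluate the test (ICC, SEM, repeated-measures ANOVA, Spearman correlation,
paired/independent comparisons). A synthetic-scene generator with analytic
ground truth makes every stage verifiable without access to real recordings.

## Target geometry

The physical target is modelled as a polyline on the board plane
(`zigzag_pattern()`): a 1 mm thick black line of total arc length 1 m on a
420 x 297 mm board. The apex coordinates of the printed target are not fixed
by the test description, so the pattern is parameterized: `n_segments` equal
segments across a horizontal `span_mm`, with the vertical rise of each
segment solved from the trace-length constraint
(`rise = sqrt((trace/n)^2 - (span/n)^2)`). The defaults (5 segments over a
400 mm span, rise 183.3 mm) honour every stated physical constraint —
A3 board, 1 mm line, 1 m trace, horizontal orientation, center cross at the
polyline midpoint — but are not claimed to match any particular printed
specimen; all geometry-dependent quantities are computed from the model, so
a different apex layout can be supplied as JSON.

Coordinates follow the raster convention everywhere: origin top-left,
x rightward, y downward, pixel centers at integer coordinates starting at
(1, 1); board coordinates are in mm with the same orientation.

## Corner detection and calibration

The camera sits behind and lateral to the shoulder, so the board is viewed
with mild perspective and the pixel-to-board mapping is a projective
homography. Four reference points are detected once per session from the
drawn line itself: the image is converted to grayscale (luma weights), dark
pixels are thresholded (Otsu by default) within the board region — found as
the row-filled hull of green-dominant pixels — and the four L1-extreme dark
pixels (argmin x+y, argmax x−y, argmax y−x, argmax x+y) are taken as the
corners. For a zig-zag these extremes sit on the outermost apexes, not on
the bounding-box corners, and the model predicts their mm positions exactly
(`pattern_corners()`), which is what the homography is fitted to.

Two practical refinements matter at 720p:

* **Occlusion-robust corners.** The dot itself occludes the line wherever it
  currently is — including the start terminus, which *is* one of the extreme
  corners, during the pre-trial dwell. Since occlusion can only shrink the
  dark line, `detect_corners_stream()` samples a handful of frames across
  the recording and keeps, per corner, the most extreme candidate.
* **Line registration.** A corner pixel is quantized to the grid, and a
  half-pixel corner error displaces the interior mapping by a few tenths of
  a millimetre. `refine_calibration()` therefore registers the full drawn
  line to the model: dark pixels are mapped to mm and the eight homography
  parameters are optimized (Nelder–Mead) to minimize their mean squared
  distance to the polyline, with the corner correspondences as a weak anchor
  that pins down the scale. On synthetic scenes this reduces the mean
  interior mapping error from ≈ 0.4 mm to below 0.1 mm.

## Dot detection and the contact rule

Laser dots are saturated red blobs, often with a blown-out white core. A
pixel is a dot candidate when `R ≥ t_abs` and `R − max(G,B) ≥ t_margin`
(defaults 0.5 and 0.2 on a [0, 1] scale) or when `R ≥ 0.97` (the white
core). Artifact clearing is a 3 x 3 morphological opening, an area band-pass
(10–5000 px), and keep-largest; the surviving component is then recovered at
its full pre-opening extent (opening-by-reconstruction) so the rim is not
eroded. The thresholds are declared defaults tuned on the synthetic scenes,
not values inherited from any particular recording setup; all are
configurable in `run_config()`. A frame without a surviving component is a
valid "not detected" observation — undetected frames are never silently
interpolated (an explicit, logged gap-bridging option exists for
trajectories, off by default).

"Touching the line" is evaluated in pixel space: the dot's pixel set must
share at least one pixel with the rasterized line mask (pixels whose centers
map within half the line width of the polyline). Sampling both shapes at
pixel centers loses, on average, about a quarter pixel of area contact, which
at 720p would bias Acuity low by 1–2 points at realistic tremor levels. The
mask is therefore widened by an automatic tolerance of **one eighth of the
pixel pitch** at the board center (≈ 0.06 mm at 2.2 px/mm); on synthetic
scenes this centers the frame-level contact decision on the analytic rule.
The tolerance can be overridden in mm (including to 0) via
`on_line_tol_mm`.

## Trial segmentation, Acuity and Speed

The trial window is derived from the dot's distance to the trace termini:
the start frame is the last frame of the first run of at least
`dwell_frames` (default 5) consecutive frames within `radius_mm` (default
10 mm) of the start terminus — i.e. the moment of departure — and the end
frame is the first frame of the first subsequent such run at the end
terminus. The dwell requirement suppresses flicker when the dot hovers at
the radius. Which terminus is "start" follows from the drawing direction
(clockwise = left-to-right starts at the left terminus).

**Acuity** is `100 × on-line frames / all frames` within the window.
Undetected frames count in the denominator (and as off-line) because the
outcome is defined over trial *time*; a `detected`-only denominator is
available as a config switch, and the per-trial record always reports
`n_frames_total` and `n_frames_detected` so either convention can be
recomputed.

**Speed** is reported in two modes. The default `arc` mode divides the arc
length of the detected centroid trajectory (gaps bridged by straight
segments) by the trial duration. The trajectory is *not* smoothed by
default: the centroid's estimation noise is ≈ 0.05 mm/frame, an order of
magnitude below genuine frame-to-frame lateral motion, and a 3-frame moving
average was measured to clip that genuine wiggle and bias speed about 5 %
low; `smooth_window` re-enables smoothing if wanted. The `nominal` mode
divides the 1 m trace length by the duration, for comparison with
protocols that define speed that way. Both are written to the trial CSV.

## Reliability statistics

All repeatability statistics operate on a subjects x trials matrix per
condition (hand x anatomical direction; rows with missing trials are dropped
listwise and counted). A single two-way sums-of-squares decomposition feeds
both the ICC and the repeated-measures ANOVA:

* **ICC.** The test's reliability is conventionally reported as a two-way
  single-measures ICC, but the label "two-way random, consistency" mixes two
  conventions (absolute agreement ICC(2,1) vs consistency ICC(3,1)). Rather
  than guess, `icc()` computes **both forms** and
  `reliability_report()` prints them side by side, with consistency as the
  default headline. Confidence intervals use the F-distribution method
  (exact for consistency, Satterthwaite for agreement), verified against an
  independent variance-components implementation.
* **SEM.** The standard error of measurement is computed from
  consecutive-trial differences: each subject's trial 2 − trial 1 and
  trial 3 − trial 2 differences are stacked into one vector and
  `SEM = SD(vector) / sqrt(2)`; the chi-square interval on the SD gives the
  CI. The stacking (pooled, vs averaging per-pair SEMs) is a documented
  choice with a flag for the alternative.
* **RM-ANOVA** over the trial factor (sphericity assumed) flags systematic
  bias such as learning across trials; a zero-residual matrix with a
  non-zero trial effect is reported as a perfect systematic effect rather
  than an arithmetic error.
* **Spearman correlation** (mid-ranks, t-approximation p) quantifies the
  speed–accuracy trade-off; **paired/Welch t-tests** compare hands and pain
  groups, with degenerate zero-variance contrasts flagged instead of
  mis-reported. A **Shapiro–Wilk gate** mirrors the usual
  parametric-vs-rank decision. No multiplicity correction is applied by
  default (matching common practice for this design); a Holm flag exists.

## The synthetic-scene generator

`generate_trial()` renders the recording conditions the scoring chain is
designed for: a 1280 x 720 px, 30 fps view of the green board and black
line under a mild perspective warp, with a red, white-cored dot advancing
along the trace. Its components, and what they emulate:

* **Speed profile**: per-frame tangential speed `N(67, 8)` mm/s (floored at
  1). The mean sits at the fast end of the 15–45 s per-trial range observed
  for this task, giving ≈ 15 s of movement plus two 1 s terminus dwells.
* **Lateral error**: a stationary AR(1) process across frames
  (`sd = lateral_sd_mm`, lag-1 correlation 0.9 at 30 fps). Real tremor and
  corrective drift are strongly autocorrelated; white noise would
  unrealistically shred the on/off-line run structure the classifier sees.
* **Rendering**: the dot and line are drawn with pixel-area coverage
  blending (anti-aliasing). A binary center-in-shape rasterization would
  shrink every mark by about half a pixel and systematically bias the
  contact statistics; coverage blending is also what a camera integrating
  over sensor pixels produces. Additive Gaussian pixel noise (SD 0.008)
  models sensor noise.
* **Ground truth**: the true dot center per frame, the contact flag
  `|lateral error| ≤ dot radius + line half-width`, the trial window
  obtained by applying the segmentation rule to the true trajectory, the
  true arc length, and the true on-line fraction.

The generator reproduces bit-identical scenes from its seed (per-frame noise
uses pre-drawn sub-seeds, so frames are identical regardless of access
order).

What the generator does **not** emulate — and hence what passing its checks
does not establish for real recordings: motion blur and rolling shutter,
lens distortion, lighting gradients and shadows, specular glare on the
board, hands or hair occluding the view (occlusion is representable as
missing detections but is not rendered), camera shake, and compression
artifacts from lossy video codecs. The contact ground truth is the lateral
offset rule above; near apexes a dot can genuinely touch the adjacent
segment while its lateral offset against its own segment exceeds the
threshold, so frame-level agreement is evaluated outside a half-pixel
ambiguity band around the contact threshold.

`generate_cohort()` simulates the full study design (left/right hand, both
draw directions, three trials: 12 trials per subject) directly at the
outcome level: subject baseline acuity `N(70, 8)`, subject x condition
effects (SD 4), residual trial noise (SD 5.5, chosen so the SEM lands in
the 5–6 range typical for this outcome and the consistency ICC near 0.7),
preferred speed `N(40, 10)` mm/s coupled negatively to acuity (0.4 points
per mm/s) to produce the expected speed–accuracy trade-off, and optional
dominant-hand gain, hand-pain deficit and per-trial learning effects.

## Numerical choices and degenerate inputs

* Homographies are fitted by the exact 4-point DLT; degenerate (collinear or
  duplicated) corners raise errors rather than returning unstable fits.
* Otsu's threshold is computed on the board region only, so dark clutter
  outside the board cannot masquerade as line pixels; images with no
  contrast raise `NoPatternFound`.
* A single dark point yields four coincident extremes and is rejected as a
  degenerate quadrilateral.
* Zero-variance reliability matrices raise explicit errors (undefined ICC);
  all-equal trials give `SEM = 0`, a valid value.
* The acceptance checks in `tests/` and `scripts/acceptance.R` run the
  end-to-end loop at the full 1280 x 720 defaults with one trial per
  lateral-error level {0, 1, 2, 4} mm, twenty camera poses for corner
  detection, 200 replicates for parameter recovery and power, and 300 for
  the type-I rate: sizes chosen to keep Monte-Carlo error well below the
  tolerances being asserted.

## Known limitations

* Only frame-image directories are read directly; container formats (MP4,
  AVI) must be exported to frames upstream, e.g. with ffmpeg.
* The corner criterion assumes the camera is roughly upright: under large
  in-plane rotation the L1 extremes of the drawn line no longer correspond
  to the model's reference corners. Mild rotation (a few degrees) is
  absorbed by the line registration.
* Analysis is offline; live scoring during recording is out of scope.
* Sub-path scoring (e.g. of individual diagonal segments) is not
  implemented; scores always cover the full trace.
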
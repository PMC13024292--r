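---
title: "Cervical spine motion analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cervical spine motion analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinetrack)
```

## The problem

Dynamic lateral X-ray recordings of the cervical spine (typically
1024 x 1024 px at 15 frames per second, one fluent extension--flexion sweep
of about 10 s) can be segmented frame by frame into per-vertebra label
masks, either manually or by a segmentation model. `spinetrack` turns such
label-mask stacks into quantitative kinematics: per-vertebra rotation
traces, per-segment (adjacent-vertebra-pair) relative rotation, segmental
range of motion (sROM), motion-pattern curves, and reliability statistics
comparing a predicted mask stack against a reference one.

The package deliberately separates *substance* (tracking, metrics,
statistics) from *inputs*: it never trains or runs a segmentation model.
Masks come in; kinematics and reports come out.

## Rotation model

Vertebrae are rigid, so each vertebra `C` has one in-plane pose per frame:
a centroid and an angle `theta_C(t)` in degrees (positive rotates x towards
y in image coordinates; row-major, origin top-left, x = column). Because a
frame-wise segmentation wobbles, the package first builds one rigid *mean
shape* per vertebra per recording and then explains every frame by a
translation + rotation of that template.

The derived quantities are:

* per-frame delta: `dtheta_C(t) = theta_C(t) - theta_C(t-1)`, defined as 0
  at the first frame;
* segmental relative rotation for an adjacent pair `Ck` (cranial) over
  `Cl` (caudal): `dtheta_R(t) = dtheta_Ck(t) - dtheta_Cl(t)`;
* a Gaussian-smoothed version of `dtheta_R` (sigma = 3 frames by default);
* sROM: max minus min of the cumulative smoothed relative rotation --
  an angular excursion in degrees;
* the motion pattern: each segment's smoothed per-frame rotation plotted
  against the cumulative C4--C7 rotation, and the SSC (sequence of
  segmental contribution), the order in which segments reach their peak
  contribution along that axis.

## Mean-shape construction

The construction is an alternation (the underlying idea -- average the
aligned per-frame masks -- admits many concrete variants; the one below is
this package's):

1. initialise every frame's angle to 0;
2. resample each frame's mask into a common local window with its centroid
   at the window centre, de-rotated by its current angle (bilinear);
3. average the aligned masks; threshold at 0.5; keep the largest
   8-connected component;
4. re-fit every frame's angle to the provisional template;
5. repeat 2--4 until the mean fit overlap changes by less than `tol`
   (default 1e-3) or `max_iter` (default 10) is reached.

Numerical points worth knowing:

* **Gauge fixing.** Nothing in the alternation pins the template's global
  orientation, so after each refit the per-frame angles are re-centred to
  zero mean. Without this the template can drift a few degrees per
  iteration; with it the template sits at the recording's mean orientation
  and all reported angles are relative to that (a constant offset that
  cancels in every delta).
* **Soft template.** The *binary* template (threshold 0.5) is the
  documented product, but the tracker fits against the real-valued aligned
  average. Thresholding re-introduces jagged staircase edges whose phase is
  locked to the pixel grid; fitting against them biases recovered angles by
  up to ~0.5 degree at specific poses. The soft field has no such
  coherence. The reported fit overlap is still the Dice of the thresholded
  rasterization, so the user-facing contract is unchanged.
* **C0.** The skull base is excluded by default: its visibility across
  frames is too inconsistent for a rigid template (override with
  `allow_c0 = TRUE`).
* **Failure mode.** Fewer nonempty frames than `min_frames` (default 3) is
  an error; non-convergence returns the best iterate with a warning and
  `converged = FALSE`, mirroring the occasional real recording on which
  mean-shape construction fails.

## Angle fitting

`fit_angle()` translates the template centroid to the mask centroid and
searches for the angle maximising overlap, restricted to +-90 degrees
around the previous frame's accepted angle. The window exists because
vertebral bodies are nearly 180-degree symmetric: an unconstrained search
can lock onto a half-turn flip between frames; a window re-centred on the
previous frame makes that impossible by construction.

The search itself is deterministic: a coarse 1-degree grid scan using a
fast surrogate (template foreground points forward-mapped with
nearest-pixel lookup), then golden-section refinement of a smooth
objective. Ties on the coarse grid (crisp shapes produce plateaus) are
broken towards the previous angle, and the refinement brackets the whole
tied plateau.

The refinement objective is a *partial-volume (soft) Dice*: the bilinearly
sampled template correlated with the bilinearly interpolated mask on a
half-pixel supersampled grid. Two cheaper alternatives were tried and
rejected during development:

* thresholded-rasterization Dice (bilinear + 0.5 cut): piecewise-flat in
  the angle, so the argmax carries pixel-flip quantization noise of a few
  tenths of a degree;
* soft Dice on the integer grid without supersampling: bilinear
  interpolation smooths anisotropically depending on the sub-pixel phase of
  the mask centroid, which biased individual frames by up to ~0.5 degree.

With the supersampled soft objective, per-frame angle errors on clean
full-size phantoms are ~0.03--0.05 degrees RMS. The overlap *reported* for
each fit (and used for the low-confidence flag, default floor 0.5) is the
conventional Dice of the 0.5-thresholded rotated-template rasterization.

## Smoothing

Rotation deltas are smoothed with a discrete Gaussian (kernel truncated at
4 sigma, normalised to unit sum; symmetric reflection at the boundaries).
sigma is expressed in frames -- the series' only sampling unit -- and
defaults to 3, which at 15 fps corresponds to a 0.2 s standard deviation:
enough to suppress frame-to-frame segmentation noise while preserving the
motion trend. Missing frames are linearly interpolated before filtering
and re-flagged as missing afterwards; cumulative quantities (sROM, the
pattern's x-axis) use the interpolated values.

## Segmentation metrics

`dsc`, `iou` and `hd95` follow their standard definitions; the package
enforces the algebraic identity `DSC = 2 IoU / (1 + IoU)` in its tests.
HD95 details that the standard definition leaves open:

* boundaries are mask pixels with at least one 4-neighbour outside the
  mask (the image border counts as outside);
* distances come from an exact Euclidean distance transform
  (Felzenszwalb--Huttenlocher), and the tests verify equality with an
  exhaustive all-pairs oracle to 1e-9;
* the 95th percentile interpolates linearly between order statistics, and
  the symmetric value is the max of the two directed percentiles;
* the result is in mm when a pixel spacing is known, otherwise in px and
  flagged as such (the mm acceptability flag is then `NA`).

Frames where either mask is empty for a vertebra are excluded from the
per-vertebra mean +- SD and reported separately: a missing detection is a
different failure than a poor overlap, and scoring it 0 would conflate the
two. Acceptability flags use DSC >= 0.8 (stricter than the usual 0.7, to
protect downstream rotation accuracy), IoU >= 0.7, HD95 < 16 mm (about a
vertebral body diameter).

## Reliability

Agreement between predicted and reference segmental rotation series is
ICC(3,1): single-rater, two-way mixed effects, *consistency* definition,
computed from the ANOVA mean squares as
`(MS_R - MS_E) / (MS_R + MS_E)` for k = 2 raters, with the standard
F-based 95% confidence interval. Consistency (not absolute agreement) is
the right definition here because a constant angular offset between two
mask sources is an artefact of template orientation, not a disagreement
about motion. Values above 0.6 are flagged acceptable, above 0.8
excellent.

The series compared is the smoothed per-frame `dtheta_R` (a `cumulative`
option compares cumulative series instead; per-frame is the default
because the pattern analysis itself is per-frame). Per-segment tables
report the mean and (min--max) range across recordings. Two sensitivity
filters can drop (recording, segment) pairs before summarising: reference
sROM strictly below 4 degrees (at 4.0 a segment is retained -- "below"
is read strictly), and low visual quality flags. Both mirror standard
practice: when a segment barely moves, true inter-frame motion is
comparable to segmentation noise and the ICC is dominated by that noise.

Pearson correlations between per-recording ICC and the mean/median/SD of
each segmentation metric are reported with two-sided p-values; p-values
are never used to filter.

## The synthetic phantom

`generate_phantom()` produces the test substrate: an articulated chain of
eight rounded rectangles (C0 at the top, C7 anchored at the bottom)
stacked along a mildly lordotic spine, rasterized at 1024 x 1024 px for
150 frames by default. Kinematics are analytic: sweep progress follows a
smoothstep from 0 to 1; each segment's rotation is a raised-cosine bump in
sweep progress with configurable excursion and peak position, clamped so
its support stays inside the sweep (the programmed excursion is therefore
exact). Vertebra poses follow by forward kinematics; rotations are
positive in the package's angle convention.

Default contributions (degrees at peak position): C0-C1 2 @ 0.95,
C1-C2 3 @ 0.90, C2-C3 5 @ 0.75, C3-C4 6 @ 0.65, C4-C5 10 @ 0.80,
C5-C6 8 @ 0.50, C6-C7 6 @ 0.20; total sweep 40 degrees. The C4--C7 values
and peak order are the stated default scenario; the upper-segment values
were chosen once to complete the 40-degree sweep with a plausible
cranial-late pattern and to include one deliberately low-motion segment
(C1-C2, 3 degrees) so the sROM filter and its reliability consequences can
be exercised. They have not been revisited since.

Degradations emulate what spoils real recordings: boundary jitter
(pixels within `jitter_px` of a label's boundary are resampled at random,
never clobbering other labels), an occlusion band (probabilistic deletion
of label pixels inside a horizontal band -- shoulder overprojection), and
whole-label dropout. All randomness is seeded; a fixed config reproduces
the stack bit-exactly. Truth fields always describe the clean kinematics.

What the phantom does *not* emulate: anatomical vertebra contours,
projective X-ray physics, bone texture, out-of-plane motion, coupled
translation, and segmentation-model failure modes with spatial structure
(e.g. consistent over-segmentation at one anatomical landmark). A green
end-to-end test therefore establishes that the *pipeline* recovers known
rigid kinematics from labelled rasters under boundary noise -- not that
any particular segmentation model is reliable on clinical data.

## Motion pattern and SSC

The pattern's x-axis is the cumulative smoothed C4--C7 rotation inside the
analysed frame interval, zeroed at the interval's first frame (the
interval defaults to the whole recording; the package does not segment
flexion/extension phases automatically). Each segment's peak contribution
is the extremum of its smoothed per-frame rotation in the direction of
motion; the SSC orders segments by the x-position of those peaks, ascending,
so reversing the motion direction reverses the SSC. Segments peaking within
one frame of each other are ordered cranial-first and flagged as ties.

## I/O formats

Canonical mask storage is uncompressed multi-page 16-bit grayscale TIFF
plus a human-readable `key: value` sidecar (`<stem>.meta`) holding frame
rate, pixel spacing, quality flags and the label map; a directory of
lexicographically ordered grayscale PNGs is accepted as an input dialect
and can also be written. Both codecs are implemented inside the package
(no external image library is required), support 8- and 16-bit unsigned
data, and round-trip bit-exactly; the TIFF reader accepts both byte
orders. Trace tables are long-format TSV with empty cells (never zeros)
for missing frames.

## Parameters at a glance

| Parameter | Default | Unit | Why |
|---|---|---|---|
| angle window | +-90 | deg | prevents half-turn flips between frames |
| coarse step | 1 | deg | grid resolution before refinement |
| refine tolerance | 0.01 | deg | golden-section termination |
| smoothing sigma | 3 | frames | noise suppression vs. trend preservation |
| sROM filter | 4 | deg | below this, motion is comparable to noise |
| DSC / IoU flags | 0.8 / 0.7 | -- | stricter DSC to protect rotation accuracy |
| HD95 flag | 16 | mm | about one vertebral body diameter |
| ICC flags | 0.6 / 0.8 | -- | acceptable / excellent |
| mean-shape tol, max_iter | 1e-3, 10 | -- | alternation stopping rule |
| min frames per mean shape | 3 | frames | fewer frames cannot average noise away |

## Known limitations

* Tracking is 2D rigid rotation about the mask centroid; translation is
  not jointly optimised and out-of-plane motion is invisible.
* The extension phase must be supplied by the caller; there is no
  automatic phase segmentation.
* ICC assumes the two series are frame-aligned; no temporal registration
  is attempted.
* The phantom's rounded-rectangle geometry makes half-turn flips easier to
  provoke than real vertebral contours would; the +-90-degree window is
  doing real work in the tests.
* With two raters and short recordings the F-based ICC confidence
  intervals are wide; the per-segment (min--max) range across recordings
  is usually more informative than any single CI.
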
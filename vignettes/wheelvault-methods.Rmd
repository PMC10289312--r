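---
title: "wheelvault: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wheelvault: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheelvault)
```

This vignette explains the science the package implements, the conventions
it fixes, and the choices made where the design was genuinely open. It
states no empirical result that the test suite or the acceptance script do
not themselves compute.

## The problem

In the wheel-gymnastics vault, judges deduct from a perfect execution score
of 6.0 for every error between the take-off and the final position before
the thrust (Unit 2 of the exercise). The deductions hinge on movement
features a 2D side-view camera can capture: how long the gymnast stays on
the wheel, and the body geometry at three poses — take-off, pike-mount, and
just before the thrust. The package estimates those deductions from the
outputs of standard vision models (dense optical flow, wheel/gymnast
segmentation masks, 25-keypoint pose estimates), and extracts the
threshold rules that drive them.

## Coordinate and direction conventions

Raster data (masks, flow) use image convention: row 1 is the top of the
frame and flow `v` is downward-positive, as stored in `.flo` files.
Everything analytic uses *analysis coordinates*: x rightward, y upward.
The conversion happens exactly once, at read/summarise time.

Flow direction is θ = atan2(−v, u) mapped to [0°, 360°), so upward motion
is the open interval (0°, 180°) and downward motion (180°, 360°). Frames
whose median direction is exactly 0° or 180°, and frames with no moving
pixel, are classified neither upward nor downward and break the runs the
detectors look for. (The inequality bands are open; 90° and 270° lie
strictly inside them and are ordinary upward/downward frames.)

The median over a flow field is the ordinary (non-circular) median over
*moving* pixels, those with magnitude strictly above `eps` (default
1.0 px/frame). Restricting to moving pixels keeps the static background
from washing out the gymnast's motion; the choice of the plain median over
a circular one follows the detectors' published angle-band formulation,
which never wraps around 0°.

## Detector parameters

| parameter | default | unit | role |
|---|---|---|---|
| `window` | 30 | frames | upward run proving the take-off jump (0.5 s at 60 fps) |
| `eps` | 1.0 | px/frame | moving-pixel threshold for flow medians |
| `min_contact_s` | 0.5 | s | contact run qualifying the start of time on the wheel (strict >) |
| `lookback` | 10 | frames | downward frames required before the thrust (≈ 0.2 s) |
| `mag_lo`, `mag_hi` | 5.5, 15 | px/frame | band on the peak lookback magnitude, rejecting the faster Unit-3 landing |

Two ambiguities had to be fixed:

* **The thrust frame.** "The corresponding frame" of the downward-to-upward
  transition could be the first upward frame or the last downward one. The
  package returns the first upward frame — the earliest frame evidencing
  extension; the choice only shifts the time on the wheel by one frame
  (1/60 s).
* **The pike-mount search range.** Its lower bound is taken to be the
  take-off (exclusive), not the start of the recording, so run-up frames
  can never win the barycenter-height argmax. Ties go to the earliest
  frame.

Contact between the lower body and the wheel is tested after dilating the
lower-body mask by one pixel (8-neighbourhood): segmentation masks of
distinct objects rarely overlap, and touching-but-not-overlapping is
exactly what sole contact looks like. The lower body is the part of the
gymnast mask trailing its barycenter x (to the right for leftward travel).

## Features

Joint angles are the arc cosine of the normalised dot product of the two
limb vectors at a joint, in [0°, 180°]. The shoulder (elbow–shoulder–hip)
and hip (neck–hip–knee) triples are the published ones; the remaining
triples follow the adjacent-joint chain: neck = (nose, neck, hip),
elbow = (shoulder, elbow, wrist), knee = (hip, knee, ankle),
ankle = (knee, ankle, toes), with "toes" the big-toe keypoint of the
25-keypoint layout (the most distal stable foot point). Angles are 2D —
the source method is 2D, and Category-B vaults involve no twisting.
The two level features are y-differences in analysis coordinates (positive
= first body part higher), and time on the wheel is the contact-to-thrust
frame difference divided by fps. Keypoints at the contact-start frame are
not used: that frame contributes only through time on the wheel.

A performance with any missing keypoint (confidence 0 or absent) at a
scored frame is discarded, and every discard is enumerated in the pipeline
report.

## The forest

The regression forest is implemented in the package (no tree library in
the dependency set provides MSE-split CART with rule extraction):
bootstrap-bagged binary trees, each split maximising the decrease in the
sum of squared errors over midpoints of distinct feature values, grown to
purity. Unstated hyperparameters default to common library behaviour for
regression forests: 100 trees, unlimited depth, all features considered at
every split. Importances are mean decrease in impurity, normalised to sum
one per tree and averaged over trees; the selection comparator at the 0.1
threshold is inclusive (≥). Two numerical details matter: a midpoint of
two adjacent floating-point values can round up to the larger one, in
which case the split threshold falls back to the smaller value; and a
split that fails to separate the node (possible only through such
rounding) converts the node to a leaf.

Validation is a day-wise sequential split (default: the last two recording
days are the test set). Random splits would let the model learn the
athlete's day-to-day form — the day, not the movement, would predict the
deduction.

The single-feature baseline defaults to ordinary least squares; the source
method's "single regression model" family is unstated, so a single-feature
forest is provided as an alternative. OLS is the default because it is the
stronger null: if a straight line through one feature already matches the
forest, the remaining features add nothing.

## Hypothesis tests

`assign_groups` crosses two threshold conditions (I = both, II = first
only, III = second only, IV = neither), honouring the printed comparator
senses: "within t" is inclusive (≤), "over θ" exclusive (>). The same
machinery serves the deduction-maximising analysis by choosing the
reference cell accordingly.

Mann–Whitney U uses midrank ties; the exact two-sided p (no ties, and at
most `exact_cap` combinations) is twice the smaller tail probability of
the exact U null, capped at 1, with p = 1 when U sits exactly at its null
mean. Otherwise the normal approximation with tie correction and ±0.5
continuity correction applies. Sidedness was not stated in the source;
two-sided is the default everywhere.

Dunnett's many-to-one test uses pooled-variance t statistics and the
k-variate t distribution with the standard correlation structure
λᵢλⱼ, λᵢ = √(nᵢ/(nᵢ+n₀)). The analytic backend integrates the
multivariate t (`mvtnorm`); a Monte-Carlo backend (default 100 000 draws,
fixed seed) reports the adjusted p with its binomial standard error. With
one treatment group both reduce to the two-sample pooled t test.

## The synthetic world

The generator is a stated world, not a dial. Each performance scripts
seven phases — run-up (40 frames), crouch (8), jump to the pike apex (34),
descent onto the wheel (16), ride (duration set by the drawn time on the
wheel), squat (10) and thrust extension (6) — on a 160×120 raster at
60 fps, with the wheel drawn as a static annulus and the gymnast as a
thick-stroke left-side stick figure. Flow fields equal the rendered
per-pixel displacement (nearest-segment assignment, velocities
interpolated along each limb) plus i.i.d. Gaussian estimator noise over
the whole field.

Defaults, chosen once:

* **Ride times** uniform on 3–7 s, so every band of the regulation
  deduction (0 below 3 s; ramps 0.1→0.2 over [3,4], 0.3→0.4 over [5,6];
  0.5 above 6 s) is populated. The unprinted 4–5 s band is filled by
  linear interpolation 0.2→0.3 — the unique continuous monotone
  completion matching the printed endpoints — and ramps are linear within
  bands so the regression sees a learnable gradient whose endpoints still
  match the regulation.
* **Pike knee angles** uniform on 145–180°, around the 162.5°
  straight-leg threshold, so feature-recovery tests have a planted rule
  at a known boundary.
* **Knee penalty rate** 0.015 deduction/degree below threshold: bent knees
  can cost up to ≈ 0.26, deliberately second to the 0–0.5 time-on-wheel
  ramp, mirroring the importance ordering the method reports on real
  mounts (FI ≈ 0.8 vs 0.16).
* **Judge noise** sd 0.05 per judge (i.i.d. Gaussian, clipped to [0, 6]),
  half the judges' 0.1 scoring grain.
* **Flow noise** sd 0.3 px/frame per component; **pose jitter** sd 3° on
  the non-planted pose parameters, so the 19 nuisance features vary
  without influencing the target.
* All randomness flows from one seed through counter-derived
  per-performance substreams; results do not depend on evaluation order.

Scale caveat: the 5.5–15 px/frame thrust band is calibrated to
full-resolution footage. Rather than rescaling the band, the scripted
squat reaches a peak median magnitude inside it (≈ 7–8 px/frame on the
small raster) — a deliberately stylised, fast-but-shallow squat.

What the generator does *not* emulate: photorealistic appearance,
biomechanically validated dynamics, segmentation/pose estimation failures,
camera motion, a rolling wheel (the mount is performed on a
near-stationary wheel; sub-pixel drift would fall below the flow epsilon
anyway), and 3D kinematics. A green test therefore establishes that the
*rules and estimators* are implemented correctly and recover planted
structure under modest noise — not that the pipeline is robust to real
segmentation artefacts. One geometric concession follows from the
simulator's invariant that wheel and gymnast masks stay disjoint until
sole contact: real gymnasts grip the rims (their 2D masks would overlap),
so the synthetic pike keeps the hands hanging clear of the wheel, below
the feet at the apex so both level features stay positive.

## Degenerate inputs and numerical choices

Readers reject rather than coerce: wrong `.flo` magic or truncated
payload, non-25-keypoint poses, mask resolution or label mismatches, and
scrambled feature-table headers are all errors. Multi-person pose frames
keep the detection with the highest mean confidence and log the choice.
Zero-length limb vectors, empty masks, empty test sets, zero pooled
variance and constant regression targets raise classed conditions; R²
with zero test variance is flagged undefined rather than returned as
±Inf. Feature tables are written with 17 significant digits so doubles
survive the CSV round trip bit-exactly.

## Known limitations

* The synthetic world's geometry is stylised (wheel smaller than life
  relative to the gymnast, stick-figure silhouette); its event detection
  margins are comfortable by construction, so detector *robustness*
  claims are limited to the modelled noise.
* Real-data headline numbers from the source study (R² 0.79 on 26
  held-out performances, importances 0.798/0.161) depend on a private
  video corpus and are reproduced here only in qualitative shape.
* The per-day performance counts of the original corpus are
  unrecoverable (108 recorded videos vs a 74/26 split); the generator's
  8 × 13 default is one consistent choice.
* Dunnett's Monte-Carlo backend reports its standard error; at p-values
  near machine zero the analytic backend saturates at 0.
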
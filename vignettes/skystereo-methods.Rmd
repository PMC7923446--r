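---
title: "Rotated-axes stereovision for wildlife monitoring: model, uncertainty and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotated-axes stereovision for wildlife monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skystereo)
```

## The measurement problem

A vertical stereo rig watching the sky over a runway must detect a flying
object, estimate how far away and how high it is, and decide whether it is
a small, medium or large bird. In classical stereovision both optical axes
are perpendicular to the baseline; on a vertical mast that aims the cameras
at the horizon. The configuration modeled here rotates both (parallel)
optical axes by a common angle $\alpha$ away from the perpendicular to the
baseline, so one installation can point its common field of view at any
elevation. `skystereo` implements this geometry end to end together with a
synthetic scene generator, so every stage can be tested without cameras,
drones or weather.

## Geometry and conventions

All angles are degrees at API boundaries and radians internally. Pixel
coordinates along the disparity axis are **signed with origin at the image
center**; image rows map to signed pixels by $y = y_0/2 - \mathrm{row}$.
C1 is the upper camera and C2 sits a baseline length $B$ below it; the
signed lateral world coordinate is positive toward C2's optical axis. An
object between the two axes therefore has $y_1 > 0$, $y_2 < 0$ and positive
disparity $y_1 - y_2$. (Field descriptions of this geometry often index
pixels $0..y_0$ from one sensor edge; the mapping is
$y_{\mathrm{edge}} = y_{\mathrm{centered}} + y_0/2$, but which edge is
"top" is convention-dependent, which is why worst cases below are always
evaluated at *both* extremes $\pm y_0/2$.)

With pixel scale $k = (y_0/2)/\tan(\varphi_0/2)$ the forward projection of
an object at plane distance $D$ and lateral offset $L$ is

$$y_1 = k\,L/D, \qquad y_2 = k\,(L - B\cos\alpha)/(D + B\sin\alpha),$$

and the closed-form inverse implemented by `triangulate_distance()` is

$$D = \frac{B\cos\alpha\, y_0}{2\tan(\varphi_0/2)(y_1-y_2)}
      + \frac{B\sin\alpha\, y_2}{y_1-y_2}.$$

The same distance is computed on every call through the equivalent
ray-angle form $D = B(\cos\alpha - \sin\alpha\tan\varphi_2) /
(\tan\varphi_1 + \tan\varphi_2)$ and agreement to $10^{-9}$ relative is
asserted; substituting the forward projection recovers $D$ exactly (a
property the test suite checks on random configurations).

**Altitude.** Two altitude estimators are provided deliberately. The
textbook closed form $H = D\cot(\varphi_0/2 + \varphi_2)$
(`altitude_eq10()`) references neither $\alpha$ nor the mount height, and
its angle convention cannot be reconciled unambiguously with the rig
geometry, so it is kept exactly as printed but is not used internally.
`altitude_from_ray()` instead intersects the camera ray with the object
plane in the world frame, $H = h_{\mathrm{mount}} + D\sin\alpha -
L\cos\alpha$; it inverts the forward model exactly and is what
`triangulate_distance()` reports. We do not claim to know which form any
particular field prototype used.

**Disparity floor.** Observations with $y_1 - y_2 < 1$ px are rejected as
non-triangulable rather than mapped to enormous distances: the uncertainty
model below diverges there, so such detections carry no usable range
information.

**Rounding.** All pixel quantization is round-half-away-from-zero
(`round_half_away()`), fixed across platforms so rendered fixtures are
bit-reproducible. Table-style outputs use the same rule at the printed
precision.

## Quantization uncertainty and baseline selection

Integer pixels make the distance a discrete function; one quantization step
is, by the exact-differential method,

$$\Delta D = \left[\frac{y_0\cos\alpha}{2\tan(\varphi_0/2)}
  + y_2\sin\alpha\right]\frac{B}{(y_1-y_2)^2} \equiv \frac{D}{y_1-y_2}.$$

The identity between the two forms is asserted at machine tolerance on
every call. For $\alpha > 0$ the uncertainty grows with $y_2$ as well as
with distance — object elevation matters, not just range.
`uncertainty_surface()` evaluates $D$ and $\Delta D$ over the integer
$(y_1-y_2, y_2)$ grid; a brute-force check in the test suite confirms that
for all true positions within 50 m, the quantized pipeline's distance error
never exceeds $\Delta D$ evaluated at the quantized observation.

`baseline_sweep()` supports choosing the shortest baseline that meets an
uncertainty target at the range limit: for each candidate $B$ it reports
the smallest integer disparity whose distance is within the limit and the
uncertainty there, per $y_2$ extreme. At fixed true distance
$\Delta D \propto 1/B$, so candidates order cleanly. Published worst-case
figures for this class of rig (tens of meters at 300 m) depend on the
pixel-indexing convention of the reporting tool; under the center-origin
convention used here the corresponding worst cases at 300 m for $B = 1$ m
fall between about 60 and 110 m depending on which $y_2$ extreme is taken,
so we report both extremes and treat single published numbers as
convention-specific rather than targets.

**Size uncertainty.** The metric width mapping $P_W = D\,p_W\,
\mathrm{SIA}/(f y_0)$ has exact differential $\Delta P_W =
(\mathrm{SIA}/(f y_0))(p_W \Delta D + D \Delta p_W)$ with a 1 px width
quantum; no closed form for this quantity is published alongside the
geometry, so defining it as the exact differential (the same method used
for $\Delta D$) is this package's choice. With the reference rig the ±band
of a 1 m wingspan stays clear of the band of a 1.67 m wingspan everywhere
inside their requested working ranges (75 m and 300 m), which is what makes
wingspan-based classing feasible at all.

## Size classification

Sizes are summarized by the isosceles-triangle area
$O_{\mathrm{approx}} = P_W P_H / 2$ (base = wingspan, height = body
height). The class boundaries derive from reference species: the common
buzzard (1.1 m × 0.4 m → 0.22 m²) separates small from medium, the red
kite (1.45 m × 0.66 m → 0.4785 m²) separates medium from large. `Ob2` is
kept at full precision by default (it derives from species dimensions, not
from its rounded printed form); `boundaries_from_species(rounded = TRUE)`
gives the conventional 0.22/0.48 pair. Boundary values fall in the larger
class — "at least buzzard-sized" counts as medium, "at least kite-sized" as
large — erring on the hazardous side. Per-event classes use each
detection's own area; scenario summaries also report the class of the mean
area, which is far more stable because size errors average out.

## Motion detection and stereo pairing

The detector is intentionally the simplest operator satisfying the
two-camera architecture: absolute difference of consecutive frames, binary
threshold (default 20 intensity levels), 8-connected components, area
filter (default 16 px² standalone). Connected components come from
`EBImage::bwlabel()`, which is 4-connected; components touching only
diagonally are merged afterwards with a small union-find, giving the
8-connectivity the contract requires. AI-based species identification and
statistical filtering of non-bird objects are out of scope; a pass-through
hook is all that remains of that stage.

Raw two-frame differencing has a known artifact: a target that moved far
enough leaves *two* blobs (old and new position), and one that barely moved
leaves an outline. `detect_moving(mask_current = TRUE)` restricts each
difference component to pixels bright in the current frame, dropping the
ghost and recovering the current silhouette's bounding box; the end-to-end
pipeline uses this mode. `pair_stereo()` matches blobs across cameras
greedily by horizontal centroid offset, subject to an offset cap and a
triangulable disparity. The geometric coordinates $(y_1, y_2)$ are taken
from **bounding-box centers**, not intensity centroids: the renderer
centers the silhouette's bounding box on the quantized projection, and a
filled triangle's intensity centroid sits $p_H/6$ below its bbox center,
which would otherwise break the exact pipeline/projection correspondence
the tests pin down.

## The synthetic scene generator

The simulator emulates the validation flights used for this class of
system: nine scenarios (`scenario_presets()`), three per target size, each
an orbit at near-constant distance and altitude. Means and spreads of
distance and altitude per scenario, target dimensions (0.24 × 0.10 m,
1.20 × 0.53 m, 1.99 × 1.04 m) and speeds (4 / 20 / 15 m/s) are the study
conditions; trajectory jitter is white noise low-passed over a one-second
window and standardized to exactly the stated spread. The horizontal
coordinate is the in-view chord of the orbit (constant-speed crossing
through the image center): no horizontal kinematics are published for the
flights, and only in-view samples enter any statistic. The default flight
duration is the chord-crossing time, capped at 60 s.

Targets render as filled isosceles triangles with pixel width
$p_W = \mathrm{wingspan}\, f y_0/(D\,\mathrm{SIA})$ — the exact inverse of
the size mapping — centered on the quantized projection, so the
classification round trip is testable to the pixel. A GPS-like reference
track adds i.i.d. Gaussian noise (default 1.0 m / 0.5 m; reference-recorder
accuracy is a free simulation parameter, configurable) to the truth.

What the simulator deliberately does **not** model: photorealistic
appearance, wing-beat pose variation, clouds/rain/illumination, lens
distortion, calibration and synchronization errors, or multiple
simultaneous targets per frame. Passing tests therefore demonstrate the
correctness of the geometry, uncertainty model and processing chain under
ideal optics — not field robustness, which for a real rig is dominated by
calibration quality and by the upstream detector's false-positive behavior.

## Evaluation statistics

`detection_efficiency()` bins time by reference distance into half-open
$(a, b]$ range bins, counting whole frames at the configured rate;
efficiency is the rounded percentage of in-bin time with a detection.
`localization_stats()` reports means and **population** (N-denominator)
standard deviations — the convention is pinned by fixtures since either
choice is defensible at these sample sizes — plus absolute and relative
accuracies of the mean. `classification_confusion()` gives the 3×3 count
matrix and per-class reliability (diagonal percentage of the row total,
half-up at one decimal).

Regression tests feed the printed validation tables of the reference field
study back through these operators. Most printed cells reproduce exactly;
a handful are one print-unit off because the original relative accuracies
were evidently computed from unrounded means, and four cells are internal
typos (their printed value contradicts the same row's printed inputs).
The tests assert exact reproduction where the table is self-consistent,
one-unit agreement where unrounded means explain the difference, and
exclude the typo cells.

## Problem sizes and numerical choices

The end-to-end acceptance run executes all nine scenarios at 15 FPS and
full 1440 px resolution with zero background noise and a fixed seed, each
for its FoV-crossing duration (5–23 s, i.e. roughly 70–350 frame pairs);
this keeps each scenario's sample count in the same range as the field
flights (31–157 samples) while the whole run stays desk-scale. The
pipeline uses `min_area = 2` because a 0.24 m target subtends ~3 px beyond
90 m; the standalone detector default of 16 px² is meant for noisy video,
where singleton noise pixels must not become blobs. Rendering intensity is
a constant 255 against a zero background; anti-aliasing is off so fixtures
are bit-exact. Property tests use $10^4$ random observations at machine
tolerance ($10^{-9}$–$10^{-12}$ relative) and a dense brute-force grid
(~40 000 true positions within 50 m) for the quantization bound.

## Known limitations

* The geometry is one-dimensional in the disparity axis plus a pinhole
  lateral coordinate; full 3-D epipolar geometry, lens distortion and
  extrinsic calibration estimation are out of scope (the modeled rig is
  assumed aligned).
* Altitude via the literal cotangent formula and via ray intersection
  disagree for $\alpha > 0$; both are exposed, and the ambiguity is
  documented rather than resolved.
* The two-frame detector cannot see a target that does not move by at
  least one pixel between frames, and its size estimates inflate or split
  when silhouettes overlap between frames — consistent with the size
  overestimation reported for field prototypes of this design.
* Published worst-case uncertainty figures tied to an edge-indexed pixel
  convention are not reproducible under the center-origin convention and
  are treated as convention-specific (both $y_2$ extremes are reported
  instead).
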
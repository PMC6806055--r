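---
title: "Forehead segmentation in thermal images: method, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forehead segmentation in thermal images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoface)
```

## The problem and the model

A thermal camera delivers a per-pixel temperature matrix. The forehead is
the facial region whose skin temperature best reflects core temperature,
but it has no sharp thermal boundary of its own, so segmenting it directly
is hard. The model behind this package is geometric: a human head seen
frontally is well approximated by an ellipse; the eyes are the warmest
points of the upper face (or, with glasses, the lenses are the coldest,
because lens materials emit far less thermal radiation than skin); and the
forehead is the cap of the head ellipse above the eyes, with a safety
margin for eyebrows and frames. Everything the pipeline does serves one of
those three assumptions:

* background/head separation by global thresholding assumes the head is
  warmer than the scene behind it;
* the ellipse fit assumes one head, roughly elliptical, dominates the
  foreground after the largest-component filter;
* the eye/lens K-means assumes the temperature extremes of the upper
  half-ellipse are concentrated at two symmetric spots.

The pipeline is deliberately cheap — a histogram threshold, one 6×6
eigen-problem, a two-cluster K-means on a few hundred points — so it can
run at camera frame rates on small embedded hardware.

## Coordinate and encoding conventions

Frames are numeric matrices indexed `[row = y, col = x]`, origin at the
top-left, y increasing downward; "upper" always means smaller y. Points
are `(x, y)` pairs. Grayscale images are integers in [0, 255]; binary
masks contain exactly 0 and 255, stored on disk as single-channel PNG. Raw
frames travel as header-less CSV (one image row per line), a small
binary container (two little-endian int32 dimensions, then row-major
float64 °C), or 16-bit TIFF with an affine decode
`°C = stored × scale + offset`. The sensor range [−20, 100] °C is enforced
at load; a value outside it is a corrupt file, not data.

## Stage-by-stage numerical choices

**Grayscale (floor rounding).** `P' = floor((P − min)/(max − min) × 255)`.
Truncation matches the integer-cast behaviour of common imaging stacks;
any consistent rounding would do, since only the ordering of intensities
matters downstream (the transform is monotone and invariant to affine
rescaling of the frame). Constant frames are rejected — with no
head/background contrast the rest of the pipeline is meaningless.

**Otsu threshold.** The 256 candidate splits `[0, M]` / `[M+1, 255]` are
scanned for the minimum weighted within-class variance, computed from
cumulative histogram moments; ties go to the smallest `M`. The test suite
checks this against a literal per-threshold brute-force oracle on hundreds
of random images. The subsequent stretch divides by `255 − M`, so
`M = 255` is rejected as an invalid threshold.

**Morphology.** Erosion uses a 3×3 square structuring element, one
iteration — the choice that produces the one-pixel inner boundary the
XOR step needs. Pixels outside the image count as background, so a head
touching the frame edge still yields boundary points there. Connectivity
is 8 for foreground components and 4 for the background when filling
holes (the standard complementary pairing; using the same connectivity
for both lets a diagonal "leak" connect a hole to the outside). Hole
filling matters for glasses: lenses are usually colder than the Otsu
threshold, so they arrive as holes in the head mask, and without filling
their contours would be fed to the ellipse fit as spurious boundary
points.

**Ellipse fit.** The conic is fitted by direct least squares under the
ellipse-specific constraint `4AC − B² = 1`, in the numerically stable
partitioned (3+3) formulation, with the data centred first for
conditioning. The fit is exact (residual below 1e−9) on noiseless points.
Geometry comes from the eigen-decomposition of the quadratic part
`[[A, B/2], [B/2, C]]`: semi-axes from the eigenvalues and the centred
constant, axis endpoints from the parametric form (and verified to satisfy
the conic), `L² = R_max² − R_min²` by construction. The rotation angle β
is the angle between the centre→apex vector and the vertical image axis,
positive when the apex lies left of the centre (clockwise head roll),
negative right, zero for a circle — where the angle is genuinely
undefined — and stored in radians (the CLI reports degrees).

**Rotation precision and eccentricity.** β's estimability degrades as the
ellipse approaches a circle: under per-coordinate contour noise of 0.5 px
on a ~200-point head contour, the estimator's standard deviation is about
0.17° for an anthropometric head (aspect R_max/R_min ≈ 1.4, R_max ≈ 38 px)
but grows past 0.35° by aspect 1.25 at smaller scales, so a 1° guarantee
only holds for realistically eccentric heads. The round-trip accuracy
tests therefore draw their ellipses from anthropometric proportions
(aspect 1.35–1.55, R_max 30–42 px, the scale at which a subject two
metres from a 140×120 camera fills the frame). Centre and axis recovery
stay within half a pixel well beyond that range.

**Inner-boundary compensation.** The erosion+XOR contour is the *inner*
pixel boundary: its pixel centres sit roughly half a pixel inside the
continuous region edge, so the raw fit systematically underestimates both
semi-axes by about that much. The pipeline adds `boundary_offset`
(default 0.5 px) to both fitted semi-axes before the region cuts. The
effect is visible in the end-to-end evaluation: without compensation the
forehead cap — a thin region whose area is sensitive to a sub-pixel shift
of its curved boundary — loses several percent of overlap with the
analytic truth.

**Half-plane cuts.** Lines are stored in normalised implicit form
`ax + by + c = 0` (vertical minor axes occur at |β| near 90°, where a
slope/intercept form degenerates; the slope view is provided when it
exists). Both cuts — at the minor axis and at the shifted midpoint — keep
pixels *strictly* on the side of the ellipse apex. Anchoring the kept side
to the apex rather than to the sign of a printed inequality makes the rule
independent of the y-axis direction convention. Pixels exactly on the
line are discarded.

**Eye/lens candidates.** The pipeline clusters pixel *coordinates*, not
intensities — two spatial centres are what the forehead construction
needs. Candidates are the extreme-temperature pixels of the upper
half-ellipse: whole intensity classes are taken from the extreme end while
the running total stays within `floor(quantile × n)` pixels
(default decile). Without glasses the stretched intensities are used
(eyes hottest); with glasses the *raw* temperatures (lenses coldest),
because the stretch clamps sub-threshold lens pixels to zero and destroys
their ordering. The upper-half region itself is the fitted ellipse
interior — not the thresholded mask — precisely so that lens pixels, which
the threshold removes, are still inside the search region.

**K-means.** Lloyd iterations, Euclidean distance, seeded from the
ellipse geometry at ±R_min/2 along the minor axis and R_max/2 along the
major axis, reflected into the retained upper half. Convergence when both
centroid shifts drop below 0.5 px (half the grid resolution), capped at
100 iterations; with the geometric seeding the phantom suite converges in
a handful. An emptied cluster is re-seeded at the candidate farthest from
the other centre and logged — never silently dropped. Output centres are
ordered left-to-right.

**Forehead cut and readout.** The midpoint of the detected centres is
moved `shift_fraction` (default 0.20) of the way toward the apex along the
midpoint→apex segment. The fraction is interpreted along that segment —
not along the major axis — because the two coincide only for perfectly
symmetric detections; the segment form is well defined always. A shifted
midpoint at or beyond the apex is a degenerate configuration and errors.
The temperature is the plain mean of raw °C under the mask (the 0/255
weighting reduces to it exactly), with the pixel count `w` reported.

**Plausibility gate.** On a frame with no head, thresholding Gaussian
noise produces a percolating blob whose algebraic ellipse fit can still
succeed. The gate requires the Jaccard overlap between the pre-fill head
component and the rasterised fitted ellipse to reach `ellipse_gate`
(default 0.6) and the fitted centre to lie inside the frame. Head
components overlap their fitted ellipse above 0.8 across the whole phantom
suite, while noise blobs score well under 0.5 (they are porous at roughly
the foreground density), so the gate separates the two regimes with a wide
margin; it is evaluated before hole filling because filling makes a noise
blob solid.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `shift_fraction` | 0.20 | – | midpoint→apex shift of the forehead cut line |
| `quantile` | 0.10 | – | fraction of upper-half pixels used as K-means candidates |
| `boundary_offset` | 0.5 | px | semi-axis compensation for the inner-contour bias |
| `ellipse_gate` | 0.6 | IoU | minimum head-component/fitted-ellipse overlap |
| `tol`, `max_iter` (K-means) | 0.5 px, 100 | | convergence of the landmark clustering |

## What the phantom emulates — and what it does not

`generate_phantom()` renders: a uniform cool background (25 °C, a
controlled room); a warm elliptical head (34 °C facial skin); two hot eye
disks (36.5 °C, radius 5 px) or two cold flattened lens patches (28 °C,
7 × 4.2 px semi-axes in the head frame — spectacle lenses are wider than
tall); optional cold occluders (a breathing-mask disc at 29.5 °C, beard
patches at 31.5 °C) on the lower face; i.i.d. Gaussian sensor noise
(default sd 0.2 °C, a conservative bound for a detector with 80 mK noise
floor); head rotation within ±60°. Eye/lens centres sit at half of each
semi-axis from the centre in the upper half — the geometry the K-means
seeding targets. Ground truth is analytic: the forehead is the ellipse
interior strictly above the line through the 20%-shifted midpoint of the
*true* eye centres, parallel to the minor axis. Defining truth by the same
geometric rule the method targets makes the end-to-end IoU a measure of
*detection* robustness (thresholding, fitting, clustering under noise and
occlusion), not of disagreement about what "forehead" means.

The phantom does **not** model: thermal gradients within facial skin (the
face is uniform apart from the stamped features), hair and ears, partial
emissivity variation, perspective or out-of-plane rotation, motion blur,
or backgrounds with head-like warm structure. Consequences worth knowing:
a real forehead is slightly warmer than the cheeks, which can only help
the eye-mode clustering; and because the phantom face is featureless, the
hottest-decile candidates of a *glasses* phantom run in eye mode scatter
uniformly, so the two centroids land near the half-region centroids at
4/(3π) ≈ 0.42 of each semi-axis — within ~4 px of the lens centres, which
sit at 0.50 of each semi-axis, for any head that fits the frame. The mode
switch still matters (an order of magnitude in landmark error), but a
large *absolute* displacement under flag inversion would require warm
facial structure the phantom deliberately lacks.

## Problem sizes used by the tests

The test and evaluation suite uses 200 phantom frames at 140×120
(rotation uniform in [−20°, 20°], 50% glasses, occluders on 30% of
frames, 0.2 °C noise), 500 random images for the threshold oracle, and
100 ellipses for the fit round-trip — sizes at which the whole suite runs
in well under a minute on one core while keeping binomial fluctuations of
the suite composition small.

## Known limitations

* One head per frame; the largest-component filter discards everything
  else, so a second person would simply be ignored (or, if larger, win).
* A background as warm as skin defeats global thresholding; nothing in a
  single thermal channel can recover from that.
* Radiometric accuracy is taken at face value: no emissivity correction
  is applied, so the reported mean is the camera's apparent temperature.
* The glasses flag is user input, as designed; inverting it degrades
  landmark placement and therefore the cut-line position.
* β is reported in [−90°, 90°]; a head rotated beyond that aliases.
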
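# thermoface

Automatic forehead segmentation and mean-temperature extraction from
single-camera thermal-infrared images.

Forehead skin temperature tracks core body temperature closely (thin skin,
dense vascularisation), which makes the forehead the region of interest for
fever screening, thermal-comfort control and psychophysiology. In practice
the region is usually outlined by hand. `thermoface` implements a fully
automatic pipeline that takes a raw temperature matrix (°C) from a thermal
camera and returns the forehead mask and its mean temperature, with the
only user input being whether the subject wears glasses.

## Method

Given a raw frame `P` (temperatures in °C, raster coordinates, origin
top-left), the pipeline runs:

1. **Grayscale**: `P' = floor((P − min) / (max − min) × 255)`.
2. **Background removal**: Otsu threshold `M` (the split of `[0, M]` /
   `[M+1, 255]` minimising the weighted within-class variance), then the
   contrast stretch `P'' = floor(255 (P' − M) / (255 − M))` for `P' > M`,
   else 0.
3. **Head mask**: binarise (positive → 255), keep the largest 8-connected
   component, fill interior holes (cold glasses lenses fall below the
   threshold and would otherwise punch holes in the head).
4. **Contour**: XOR of the mask with its 3×3 erosion — the one-pixel inner
   boundary.
5. **Ellipse fit**: direct least-squares conic fit
   `Ax² + Bxy + Cy² + Dx + Ey + F = 0` under the ellipse constraint
   `4AC − B² = 1`; centre `(x₀, y₀)`, semi-axes `R_max ≥ R_min`, focal
   distance `L = √(R_max² − R_min²)` and signed rotation `β` (positive =
   clockwise, i.e. head apex left of centre) are recovered from the conic.
6. **Upper half**: the ellipse interior is cut at the minor axis, keeping
   the half containing the apex.
7. **Eye/lens detection**: two-cluster K-means over the coordinates of the
   extreme-temperature pixels of the upper half (hottest decile without
   glasses — eyes; coldest decile of raw temperature with glasses —
   lenses), seeded at ±R_min/2 sideways and R_max/2 up from the centre.
8. **Forehead cut**: the midpoint of the two detected centres is shifted
   20% of the way toward the apex; a line through that point parallel to
   the minor axis cuts the forehead region out of the upper half-ellipse.
9. **Temperature**: `F̄t = (1/w) Σ P(x, y)` over the `w` nonzero mask
   pixels.

A plausibility gate after the fit (Jaccard overlap between the head
component and its fitted ellipse) makes head-free frames fail loudly
instead of emitting a meaningless mask.

Because recorded thermal data cannot ship with the package, a synthetic
phantom generator (`generate_phantom()`, `generate_suite()`) renders head
frames with known geometry — warm elliptical head on a cool background,
hot eye disks or cold lens patches, optional breathing-mask/beard
occluders, sensor noise — together with analytic ground truth, and
`evaluate_batch()` scores the pipeline against that truth with the Jaccard
coefficient (IoU).

## Worked example

```r
library(thermoface)

ph  <- generate_phantom(phantom_spec(seed = 7))   # 120x140 frame, no glasses
fit <- forehead_segment(ph$frame)
fit
#> Forehead segmentation
#>   frame: 120 x 140 px, glasses: FALSE
#>   ellipse: center (70.0, 58.0), axes (37.8, 26.8) px, beta 0.0 deg
#>   eye centres: (56.5, 39.0) and (83.5, 39.0)
#>   forehead: 465 px, mean temperature 34.07 degC

jaccard(fit$mask, ph$truth$forehead_mask)
#> [1] 0.9893617
```

The phantom places its head at centre (70, 58) with semi-axes (38, 27) and
eye centres (56.5, 39) / (83.5, 39); the pipeline recovers the ellipse to a
few tenths of a pixel, the eyes to sub-pixel accuracy, and the forehead
mask overlaps the analytic truth at IoU 0.99. The reported 34.07 °C is the
mean of the simulated 34 °C forehead skin under 0.2 °C sensor noise.
`coef(fit)`, `summary(fit)` and `plot(fit)` expose the fitted geometry,
diagnostics and an overlay image. A command-line interface with the same
functionality is in `inst/cli/thermoface.R`
(`segment` / `phantom` / `evaluate`).

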
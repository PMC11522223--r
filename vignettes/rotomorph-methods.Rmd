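---
title: "Visual-hull reconstruction and 3D morphometry of rotating specimens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visual-hull reconstruction and 3D morphometry of rotating specimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rotomorph)
```

## The problem

A *C. elegans* adult or embryo rolling uniformly about its long axis under a
brightfield microscope yields a frame sequence in which every frame is an
orthographic attenuation image of the same body at a different roll angle.
rotomorph turns such a sequence into a dense 3D model by shape-from-silhouette
carving, validates the model by reprojection intersection-over-union (IoU),
and extracts five morphometric phenotypes: surface area (µm²), volume (µm³),
length (µm), maximum width (µm), and the length-to-width ratio. A parametric
phantom generator stands in for the rotation hardware: it renders rotation
stacks of synthetic worms (length ≈ 1 mm, maximum diameter ≈ 50 µm) and
gastrulation-stage embryos (≈ 50 × 30 µm ovoids) with analytic ground truth,
so every stage of the pipeline can be scored against known geometry.

## Geometry and the carving model

The specimen lives in a co-rotating frame: x along the rotation axis (image
columns), (y, z) the cross-section plane. At roll angle θ a point (y, z)
projects to the image-vertical offset v = y·cosθ + z·sinθ. A silhouette's
vertical interval at column x therefore constrains the cross-section at x to
a strip in the (y, z) plane; the visual hull's cross-section is the
intersection of the strips of all contributing frames. Visual hulls are
guaranteed supersets of the body; concavities invisible in every silhouette
cannot be recovered (the fundamental silhouette limit). For an ideal convex
profile observed from N uniform directions the hull cross-section is the
regular 2N-gon with apothem r and area 2N·r²·tan(π/(2N)), which the test
suite checks at N ∈ {4, 8, 90}.

Two departures from a plain strict intersection matter in practice:

* **Quorum intersection.** A voxel survives if it satisfies all but a small
  fraction of the contributing strip constraints. The tolerated fraction is
  uncertainty-scaled: 0.5 px of silhouette boundary noise is negligible for a
  50 µm body but decisive for a 2-px tail tip, so the tolerance is
  `clamp(0.5/strip_height_px, miss_frac, 0.3)` with `miss_frac = 0.02` (about
  one corrupted silhouette in a 64-frame turn). A strict intersection erases
  sub-resolution tips because a single noisy boundary in any frame vetoes
  them.
* **Confident-extent gating** (the feature-completion rule). Each frame
  carries a confident column extent — the maximal run of columns whose
  contrast reaches `c_min = 0.3` of the best contrast the stack ever shows
  for that column. Columns outside the extent impose no constraints. A
  low-contrast tail visible only at some orientations is therefore carved
  only by the frames that actually see it, instead of being cut away by the
  frames that do not. Slices with fewer than `min_contrib = 8` contributing
  frames stay empty (two strips intersect in an unbounded rhomb). Disabling
  the gate (`gate_extent = FALSE`) reproduces the failure mode: on phantoms
  with an orientation-dependent tail fade the reconstructed length error
  degrades from ≈ 2% to > 20%.

A brute-force carver (`carve_bruteforce()`) projects every voxel into every
frame independently and must agree with the slicewise carver voxel for voxel;
this oracle equivalence is asserted in the tests on worm and embryo
pipelines.

## Silhouettes with sub-pixel boundaries

Brightfield segmentation is the stage the original workflow solves with
trained networks; rotomorph substitutes deterministic classical operators
with the same contract (clean per-frame silhouettes plus confident extents),
which keeps the pipeline reproducible and download-free. Three ideas carry
the accuracy:

1. **Stack-global thresholds.** Illumination does not change while the
   specimen rotates, so all frame thresholds derive from pooled statistics.
   Per-frame thresholds would jitter the boundary between frames, and the
   strip intersection keeps the narrowest boundary seen in *any* frame —
   frame-to-frame consistency matters more than per-frame optimality.
2. **A physical boundary level.** In an attenuation image the geometric
   silhouette edge is not at the Otsu midpoint. The boundary threshold is
   placed at the contrast level where a Beer-Lambert limb of the specimen's
   estimated half-width, passed through the imaging chain (Gaussian PSF, box
   pixel aperture, and the Wiener restoration filter's transfer function
   H/(H²+k)), crosses its geometric edge. This fraction is computed from a
   1D forward model at run time (`edge_threshold_frac()`); it is ≈ 0.35 of
   the foreground amplitude for an adult worm at 4 µm/px and ≈ 0.15 for an
   embryo at 0.5 µm/px.
3. **Sub-pixel bounds.** The threshold crossing is located by linear
   interpolation within each column and stored as continuous strip bounds;
   carving consumes these rather than the binary masks. The crossing level
   scales with the frame-local column amplitude, so a contrast fade (which
   multiplies the whole profile) does not displace the boundary.

Faint sub-resolution tips are caught by a hysteresis companion: the same
contrast smoothed at the feature scale (σ = 1.5 px) has about three times
the tip SNR, and weak evidence counts only where it connects to the strong
mask, within reach of its column support, and within the span of its nearest
detected column.

Enhancement before segmentation does background flattening (blockwise upper
quantile over non-specimen pixels, specimen-dominated blocks inpainted), a
compiled 3×3 median, optional upsampling, and Wiener deconvolution of the
PSF (`deconv_sigma_px = 1.2` px, `wiener_k = 0.05`). Deconvolution is the
classical counterpart of the learned super-resolution step: it restores
near-sharp edges, making the threshold level insensitive, and upsampling
halves the quantization scale of the rasterized silhouettes.

## Rotation kinematics

The period estimator is template matching by normalized cross-correlation:
similarity(lag) is the mean NCC between frames i and i+lag. Peak location
uses mean-subtracted, lightly smoothed frames — the static silhouette
correlates at every lag and would flatten the curve, while the rotating
internal texture (the phantom's seeded "landmark" blobs, standing in for
organelles and gut granules) carries the period. The peak is refined by
3-point parabolic interpolation, corrected for octave errors (half-lag peaks
of comparable height), and averaged across harmonic peaks when the stack
holds several turns. The reliability score is the raw-frame NCC at the
matched lag; below `s_min = 0.6`, or for a flat curve, the rotation is
declared unreliable. On phantom stacks the estimate is within 0.03 frames of
truth noiselessly and within 0.05 frames at 5% noise (the tests assert the
specified 0.5- and 1-frame bands).

Alignment removes in-plane drift without erasing shape: the mask-centroid
trace is modeled as (periodic oscillation) + (slow drift), the oscillation
captured by first and second harmonics at the known period and the drift by
a cubic; only the drift part is subtracted. Frames are shifted by integer
pixels; sub-pixel residuals are stored and applied to the strip bounds
during carving (and compensated during reprojection), never by resampling
masks. Angles follow the uniform-rotation law θᵢ = 2π(i−ref)/P over exactly
one period, justified by the small timing spread of the rotation hardware
the phantoms emulate.

## Meshing and morphometry

The occupancy grid is smoothed with a 3D Gaussian (σ = 1 voxel) and the 0.5
iso-surface is extracted by marching tetrahedra on the Kuhn 6-tetrahedron
cube decomposition. This iso-surface extractor is table-free and watertight
and consistently oriented by construction (shared cube faces are cut along
the same diagonals in neighbouring cubes), which we preferred over
transcribing the classic 256-case cube tables without a reference
implementation to check them against. Ten passes of Taubin λ|μ smoothing
(λ = 0.5, μ = −0.53) remove voxelization ripple while changing the enclosed
volume by well under 1%. On a digitized sphere the mesh area is within 0.5%
of 4πr².

The five metrics:

* **volume** — occupied-voxel count × voxel volume; the divergence-theorem
  mesh volume is the QC cross-check (they agree within 2%);
* **surface area** — sum of mesh triangle areas;
* **length** — arc length of the centerline: endpoints are end-slab
  centroids along the body's principal axis, the path is the minimum-cost
  geodesic with node costs ∝ 1/(distance-to-surface + ½)², pinned to the
  medial axis, refined by normal-slab centroid snapping (endpoints
  excluded — a cap's slab centroid pulls inward), smoothed by cubic
  smoothing splines, and extended along the terminal tangents to the
  surface;
* **maximum width** — at 100 arc positions the mesh is cut by the plane
  normal to the local tangent; the width is the maximal Feret (caliper)
  diameter of the section, a 5-sample running median guards against oblique
  cuts, and the terminal 5% of arc length is excluded at each end (cap
  artifacts); length over width gives the **ratio**. Both a centerline-based
  and an extent-based length are defensible readings; the centerline is
  canonical here because the bodies are curved.

`cross_section()` returns closed, angularly ordered transverse outlines at
any arc position, the per-strain section galleries of phenotyping figures.

## The phantom generator

Worms are tubes around a sinusoidal planar centerline with cosine end caps
(`cap_frac = 0.12` of the length per cap) and a mid-body taper
(4s(1−s))^taper; embryos are ellipsoids with a smooth low-order angular bump
field. Ground truth comes from closed forms where they exist and otherwise
from fine numerical quadrature of the continuous parametric definition —
never from the reconstruction path. Rendering simulates the optical chain in
physical order on a grid twice finer than the sensor: thickness
accumulation, Beer-Lambert attenuation (attenuation length 25 µm, contrast
0.55 of the dynamic range), Gaussian PSF blur (σ = 1.2 px; the objectives'
NA is not modelled, so this width is a free acquisition parameter), then box
integration over each sensor pixel, followed by planar background shading,
seeded drift, and additive Gaussian noise. Internal landmark blobs of extra
optical density break rotational and mirror symmetry the way real internal
structures do. The tail fade multiplies the optical density of the tail
region by an orientation-dependent floor (0.02 worst, 0.85 best); geometry
is untouched, which is what makes tail completion testable.

The reference conditions (chosen once, stated here as the package's own
study design): adults 1000 × 50 µm at 4 µm/px, 96 frames, 64-frame period;
embryos 50 × 30 µm at 0.5 µm/px, 72 frames, 48-frame period; 2% noise, zero
drift. Cohorts draw adult length 850–1100 µm, radius 22–28 µm, bend
10–50 µm, taper 0.05–0.3, and embryo semi-axes 22–28 / 13–17 µm with bumps
0.02–0.07 from fixed documented ranges. What the phantoms do **not**
emulate: internal anatomy beyond diffuse landmarks, refraction and partial
coherence of real brightfield optics, body flexing during rotation, and
non-uniform rotation. Passing tests therefore demonstrate the geometry
pipeline, not robustness to those effects.

## Validation experiments and problem sizes

Reprojection IoU compares the model, rotated to a frame's assigned angle and
projected onto the mask raster, against that frame's segmented silhouette at
viewpoints 0°–180° in 30° steps (nearest-frame matching, no interpolation).
Voxel centres are projected with no extra margin: the carving strips already
carry the ±half-pixel footprint of the silhouette rows, so adding a margin
would spill the silhouette one row outward at oblique angles.

The accuracy experiments run at sizes chosen to keep a full validation
under a few minutes of CPU: the single-specimen reference runs use 4×
enhancement upsampling (the quantization scale halves twice), the
12-specimen cohorts use 2×, and the 20-phantom parameter-recovery battery
runs the full pipeline (including meshing and morphometry) at native
resolution. Meshing and morphometry are skipped in IoU-only runs since the
reprojection uses the voxel model directly. Typical results: per-viewpoint
IoU 96–98% on the reference adult, cohort grand means ≈ 97% (adults) and
≈ 98% (embryos), and median absolute metric errors of 1–3% across the
battery — the test suite asserts the exact bands.

## Numerical choices and degenerate inputs

* Pixel coordinates are 1-based with closed column intervals, the idiomatic
  R convention.
* Rendering deposits voxels bilinearly on the fine grid; nearest-pixel
  rounding would shift the whole image a quarter pixel whenever the voxel
  lattice aligns with fine-grid boundaries.
* Boundary regularization smooths each mask's per-column top/bottom rows
  with a 5-column running median (capped at ±1 px) and stores columns as
  vertical spans — the span convention the carver uses for multi-run
  columns, which cannot be matched across angles.
* An empty carve, a failed segmentation frame, an unreliable rotation, or a
  skeleton without endpoints each raise errors with diagnostics rather than
  returning silent zeros; background-only frames are flagged and excluded.
* A sphere is a legal, degenerate specimen: its "length" is the diameter
  within 5%, and its silhouettes are identical disks up to voxel
  quantization at the limb.
* Student's pooled t is the default two-group test (Welch behind a flag);
  no multiple-testing correction is applied by default, with
  Benjamini-Hochberg available. The classifiers retain 2 principal
  components by default (decision plots are 2D); the SVM kernel is RBF with
  a linear flag.

## Known limitations

Concavities are invisible to any silhouette method; the hull is a superset
by construction. Metric accuracy inherits the segmentation's boundary
calibration, which assumes an approximately Beer-Lambert specimen — strongly
scattering or refractile samples would need a recalibrated edge model. The
alignment's harmonic-plus-cubic drift model covers slow drift and random
walks over a few periods, not jumps. Specimens whose mask spans multiple
disconnected components per frame (two animals in the crop) are out of
scope: one specimen per crop.
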
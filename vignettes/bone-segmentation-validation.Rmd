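---
title: "Semi-automatic bone segmentation and its validation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automatic bone segmentation and its validation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(boneseg)
```

## What the package computes

`boneseg` implements a gradient-based, semi-automatic pipeline for
isolating a bone from a volumetric scan, and the measurement protocol used
to quantify how repeatable that isolation is. The pipeline assumes only
that the bone/soft-tissue interface carries a strong intensity gradient —
no training data, no shape prior. Its stages map one-to-one onto exported
functions:

| stage | function | state produced |
|---|---|---|
| per-slice edge detection | `detect_edges()` | `edge_map` |
| scripted seeding | `auto_seed_from_mask()`, `initialize_slice()` | `boundary_set` |
| slice propagation | `propagate_boundary()` | `boundary_set` |
| model building | `boundary_to_pointcloud()`, `build_mesh()` | `point_cloud`, `surface_mesh` |
| registration | `icp()`, `register_models()` | `icp_result` |
| agreement metrics | `weighted_dice()`, `surface_distance()`, `compute_contrast()` | reports |

Everything is 1-based and indexed `[slice, row, col]`; physical
coordinates are `x = x0 + (row−1)·dr`, `y = y0 + (col−1)·dc`,
`z = z0 + (slice−1)·ds` (mm). The in-plane row axis (x) is, by the
phantom's construction, perpendicular to the articular face; signed
surface distances are differences along x, positive where the first model
is locally larger.

## Edge detection

`canny_slice()` is the standard pipeline: Gaussian smoothing (`sigma`, in
pixels), Sobel gradients, non-maximum suppression, hysteresis. Two
interpretation choices matter:

* **Normalization.** The high threshold is a fraction of the *per-slice*
  maximum gradient magnitude. This is the only reading under which a single
  threshold range (0.02–0.07 MRI-like, 0.15–0.25 CT-like) is usable across
  slices of varying brightness. A consequence worth knowing: slices
  containing only noise still normalize to their own maximum, so
  out-of-range slices produce dense noise edges — the pipeline therefore
  only processes the slab of slices containing bone.
* **The low threshold** is fixed at `0.4 × high`, the conventional default
  of implementations that expose a single threshold.
* **Smoothing width.** The upstream tool's quoted default standard
  deviation is 0.10, which on a pixel scale performs almost no smoothing.
  Whether that number was meant in pixels, in mm, or referred to another
  parameter is unknowable from the description, so `sigma` is exposed with
  that value documented, while every experiment in this package uses
  1.0 px, which localizes a clean step edge to within one pixel (the test
  suite checks this against an independent gradient-argmax oracle).

Non-maximum suppression breaks ties between an equal-magnitude pixel pair
asymmetrically (`>=` toward the positive gradient direction, `>` away), so
an ideal two-pixel-wide plateau yields a single line. Constant slices
return an empty edge map with a warning.

## Seeding and propagation

The interactive steps are replaced by *edit scripts* — per-slice removal
and seed-pixel lists (`edit_script()`, JSON-serializable). For phantom
experiments `auto_seed_from_mask()` builds the script a careful operator
would have produced:

* one seed per edge component overlapping the 2-px-dilated ground-truth
  bone boundary, on every fifth bone slice (`every_n = 5`, with `phase`
  offsetting the pattern — the repeatability experiments use offsets of
  one slice);
* removals pruning those components' pixels outside the dilated boundary
  (severing bridges to stray structures);
* seeds on the first and last bone slices (which the operator identifies
  explicitly before cropping), and on any adjacent slice pair whose true
  boundary moves farther than the propagation radius. Near the poles of
  the bone the cross-section grows by many pixels per 0.7 mm slice — no
  safe search radius can follow it, and these are exactly the slices where
  an operator steps in and corrects before proceeding.

`propagate_boundary()` processes slices outward from each initialized
slice; where two fronts could meet, the nearest initializer wins (ties to
the lower slice index — determinism is a design goal throughout). For each
source-boundary pixel the nearest target-slice edge pixel within
`radius_px` (default 3, ties to the smallest `(row, col)`) is pulled; the
assignment then grows along the 8-connected edge components containing
pulled pixels, clipped to within `radius_px` of the source boundary. Pure
single-pixel pulling leaves seeding-pattern-dependent holes in the
recovered ring that compound across slices; growing restores the full
boundary ring while the radius cap still prevents jumps to distant
structures (the cartilage's outer edge sits ≈ 7.5 px away at the default
resolution). Because the bone boundary is a closed curve, open-ended
chains picked up near junctions with other edges are pruned
(`radius_px` erosion passes of degree-≤1 endpoints) — the scripted
counterpart of an operator deleting stray points. A slice with no
reachable edge pixels receives an empty boundary plus a warning, and
propagation continues from the last non-empty slice.

The propagation radius trades off two failure modes: too small and the
boundary cannot follow the anatomy between slices; too large and it
captures the adjacent cartilage edge. 3 px at 0.4 mm pixels (1.2 mm)
suits patella-scale anatomy at 0.7 mm slice spacing.

## From boundaries to models

Dice comparisons operate on *filled* per-slice masks
(`boundary_to_masks()`): a one-pixel boundary ring is rasterized by
flood-filling the background from the image border (4-connected, blocked
by the 8-connected ring) — an ordering-free operation that is robust to
ring thickness and spurs. Only if a ring truly leaks does the code fall
back to ordering the pixels into a polygon (`order_contour()`: greedy
nearest-unvisited-neighbor from the smallest pixel) and scanline-filling
it. Computing Dice on filled regions rather than boundary pixels matches
the notion of segmentation agreement; on one-pixel rings the coefficient
would be pathologically sensitive.

`build_mesh()` stacks the filled masks into a binary volume, pads it,
**Gaussian anti-aliases it (sigma = 1 voxel per axis)**, and extracts the
0.5-level isosurface with linearly interpolated vertices; uniform
Laplacian smoothing (default 10 iterations, factor 0.5) is applied
identically to every mesh that will be compared. The anti-aliasing step is
a numerical necessity, not cosmetics: an isosurface of a raw binary mask
is a voxel staircase whose area overestimates a sphere's by ≈ 8 %, failing
any closed-form check; after the pre-filter the test sphere's area and
enclosed volume are both within 2 % of `4πr²` and `4/3πr³`. Isosurface
extraction uses marching tetrahedra (each lattice cube split into six
tetrahedra sharing its main diagonal; shared faces use the same global
diagonals), which is table-free and guarantees a watertight result — the
suite asserts every mesh edge is shared by exactly two faces.

`flag_cartilage_region()` marks mesh vertices within 1 mm (default) of any
cartilage voxel center or cloud point; on the phantom this reproduces the
articular facet patch on the +x side.

## Registration

`icp()` is classic point-to-point ICP: centroid pre-alignment, nearest
neighbors from a kd-tree, closed-form least-squares rigid fit
(cross-covariance SVD with reflection rejection), iterated until the rms
change drops below `tol_mm` (default 1e-6, cap 100 iterations). The rms is
non-increasing by construction and the suite checks recovery of random
rigid misalignments (≤ 10°, ≤ 5 mm) to rms < 1e-6 on noiseless clouds.

Point-to-point correspondences have a known blind spot that this phantom
exposes: on a smooth, nearly symmetric surface reconstructed from a voxel
lattice, a small rotation can slide tangentially against a compensating
translation, and the point-to-point objective can be genuinely *lower* at
that slid pose than at the true one. `register_models()` therefore runs
point-to-point ICP for the convergence basin and then a point-to-plane
refinement (linearized rigid update minimizing residuals along the target
mesh's area-weighted vertex normals), which removes the sliding mode.
Every experiment registers models this way; `icp()` remains available as
the bare algorithm. No trimming is applied by default — the simplest
contract — though the correspondence machinery supports experimenting with
it.

## Agreement metrics

* `compute_contrast()` evaluates
  `|I_bone − I_cartilage| / I_cartilage` exactly; the default phantom
  profiles were chosen so the T1-VIBE-like and DESS-like contrasts come
  out 0.95 and 0.72.
* `weighted_dice()` weights each slice's DSC by `|X_s| + |Y_s|`. The
  description "how many pixels were present in each slice" does not name
  the set; the symmetric sum is the choice that keeps the aggregate
  symmetric in its two arguments.
* `perimeter_reduce()` projects the flagged region onto the y–z plane,
  takes the convex hull of the projection as its boundary polygon, scales
  the polygon about its area centroid by `1 − fraction` (default 0.25),
  and keeps vertices projecting inside. For a circular region this scales
  the perimeter by exactly 0.75; for non-convex flagged regions the hull
  is an outer approximation — adequate for the phantom's convex facet.
* `surface_distance()` subtracts the first model's vertex-mean centroid
  from both models ("volume centroid" is implemented as the vertex mean —
  unambiguous, and within 0.1 mm of the enclosed-volume centroid on
  near-convex meshes), restricts to the perimeter-reduced flags, and for
  each analysis vertex averages *both* models' vertices within
  `radius_mm` (default 2.5) before differencing x. Averaging only the
  second model — the literal reading — biases the distance wherever the
  surface curves, because a ball average lies strictly inside a convex
  surface; on identical phantom meshes that bias is on the order of
  0.1 mm, an order of magnitude above the effects being measured. The
  symmetric form makes the identity comparison exactly zero, keeps
  A-vs-B antisymmetry, and still recovers a pure x-translation in full on
  a flat model. Note that on a curved facet an x-translation appears
  attenuated by the local `cos²` of the surface tilt — the protocol
  measures x-differences, not normal distances.

## The phantom, and what passing tests do not show

`phantom_spec()` fixes the study conditions: superellipsoid bone
(22 × 18 × 14 mm semiaxes, exponent 2.5 — flatter articular facet than an
ellipsoid), 3 mm cartilage shell on the +x facet (thickness measured along
x, which makes the x-perpendicular distance convention exact), per-modality
spacings (0.7 × 0.4 × 0.4, 1.0 × 0.3 × 0.3, 0.6 × 0.3 × 0.3 mm), nominal
intensities reproducing contrasts 0.95/0.72, additive Gaussian noise
(SD 2 for the MRI-like profiles, 10 for CT-like), seed 42. Scan/re-scan is
emulated as two noise realizations plus a 1° / 0.5 mm rigid pose
perturbation of the second acquisition. Ground-truth masks come from the
same analytic geometry and never depend on noise or seed.

Deliberate simplifications: additive Gaussian noise rather than Rician
(the algorithm is gradient-based; noise-model fidelity is secondary),
no partial-volume model, no bias fields, no motion or metal artifacts,
and an anatomy far smoother and more symmetric than a real patella.
Passing the phantom experiments therefore demonstrates the *internal
consistency* of the pipeline — edge localization, propagation stability,
meshing accuracy, registration, metric correctness — not performance on
clinical images. The smoothness actually makes registration *harder* than
reality (the sliding mode above), while the absence of texture makes edge
selection easier.

## Problem sizes and determinism

The canonical phantom rasterizes to roughly 60 × 150 × 120 voxels at the
MRI-like resolution (≈ 1M voxels, ≈ 25 000 boundary points, ≈ 100 000 mesh
vertices); a full repeatability experiment runs in seconds. The unit suite
uses a half-scale phantom for speed; half-scale agreement bounds are
correspondingly looser, and the full-scale bounds are exercised by the
end-to-end tests. All randomness flows from explicit seeds through a
locally scoped RNG, so every experiment re-run with the same configuration
reproduces its report byte-for-byte; the suite asserts this.

## Known limitations

* The propagation radius and front-merging rule are package choices; the
  original interactive procedure left them to the operator.
* The meshing route (contours → masks → isosurface) is deterministic and
  testable, but no claim is made that it matches any commercial
  reconstruction mesh-for-mesh — comparisons are meaningful at the level
  of the protocol (same operators applied to both models).
* `perimeter_reduce()`'s convex-hull boundary is exact only for convex
  projected regions.
* Manual reference segmentation is emulated, not reproduced: the package's
  comparisons quantify repeatability of the semi-automatic method against
  itself and across modalities.
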
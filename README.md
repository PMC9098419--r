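# boneseg

Gradient-based semi-automatic bone segmentation from volumetric MRI- and
CT-like images, with the complete validation tool-chain used to
characterise how repeatable such segmentations are.

## The problem

Manual segmentation of bone from MR images takes hours per scan, which
limits orthopaedic imaging studies that need patient-specific 3D bone
models (cartilage-thickness mapping, joint kinematics). A practical
alternative is a *semi-automatic* pipeline that needs no training data:

1. **Canny edge detection** per slice, with hysteresis thresholds on a
   normalized 0–1 scale (`high = threshold × max |∇I|` per slice,
   `low = 0.4 × high`), so one threshold range (≈ 0.02–0.07 for MRI-like,
   0.15–0.25 for CT-like contrast) works across slices;
2. **seeded selection**: on roughly every fifth slice an operator (here, a
   scripted edit list) breaks stray 8-connected edges and seeds the
   components lying on the bone boundary;
3. **slice-to-slice propagation**: each initialized boundary pulls the
   nearest edge pixels (within a capped radius) in the adjacent slices,
   outward from every initialized slice;
4. **model building**: tracked boundaries become a 3D point cloud and — via
   filled contour masks and a 0.5-level isosurface — a closed, smoothed
   triangle mesh.

Validation follows the protocol used for repeatability studies of such
pipelines:

* bone/cartilage **contrast**, `|I_bone − I_cartilage| / I_cartilage`;
* slice-weighted **Dice similarity coefficient** between two segmentations
  (per-slice DSC `2|X∩Y| / (|X|+|Y|)`, weighted by per-slice pixel mass);
* **rigid registration** (ICP with a point-to-plane refinement) followed by
  the **signed surface distance**: for every mesh vertex in the
  cartilage-adjacent region (after a 25 % perimeter reduction to avoid edge
  effects), all vertices of the other model within 2.5 mm are averaged and
  the difference in x (the axis perpendicular to the articular face) is
  reported as mean ± SD.

Because real patellae cannot ship with a package, a synthetic phantom
stands in: a superellipsoid bone (semiaxes 22 × 18 × 14 mm, exponent 2.5,
flattened articular facet) with a 3 mm cartilage layer on its +x face,
rendered at T1-VIBE-like (0.7 × 0.4 × 0.4 mm), DESS-like (1.0 × 0.3 × 0.3 mm)
and CT-like (0.6 × 0.3 × 0.3 mm) resolutions with modality-specific
intensities (contrasts 0.95, 0.72) and additive Gaussian noise, plus
analytic ground-truth masks.

## Worked example

```r
library(boneseg)

# one rendering, segmented twice with the seeding pattern offset by one
# slice, then meshed, registered and compared
rep <- run_experiment(experiment_config("same_scan_repeatability"))
print(rep)
#> experiment_report: same_scan_repeatability
#>   weighted DSC: 0.999811
#>   surface distance: -0.001772 +/- 0.008841 mm ( 11082 matched )
#>   ICP rms: 0.0156941 mm in 6 iterations
```

The weighted DSC of 0.9998 says the two segmentations of the same volume
agree almost pixel-for-pixel; the mean signed surface distance of
−0.002 mm over the 11 082 analyzed cartilage-facing vertices says neither
run is systematically larger. The other two comparisons:

```r
run_experiment(experiment_config("scan_rescan"))   # two noise realizations
#>   surface distance: -0.01083 +/- 0.03332 mm      # + 1 deg / 0.5 mm pose
run_experiment(experiment_config("mri_vs_ct"))     # MRI-like vs CT-like
#>   surface distance: 0.03888 +/- 0.03083 mm
```

Lower-level pieces are exported individually (`generate_phantom()`,
`detect_edges()`, `auto_seed_from_mask()`, `propagate_boundary()`,
`build_mesh()`, `icp()`, `register_models()`, `weighted_dice()`,
`surface_distance()`, …), and `inst/cli/boneseg.R` is a thin Rscript
front end (`simulate`, `detect-edges`, `segment`, `register`, `compare`,
`dice`, `experiment`).

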
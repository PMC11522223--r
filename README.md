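# rotomorph

3D reconstruction and morphometric phenotyping of rotating *C. elegans*.

A specimen rolling uniformly about an image-horizontal axis under a
brightfield microscope produces a frame sequence in which every frame is an
orthographic view of the same body at a different roll angle. `rotomorph`
turns such a sequence into a dense 3D model and quantitative shape
phenotypes:

1. **enhance** — background flattening, median denoising, Wiener
   deconvolution of the PSF, optional super-resolution upsampling;
2. **segment** — per-frame silhouettes with sub-pixel boundaries placed by a
   Beer–Lambert edge model, plus per-column confidence and the *confident
   extent* of each frame;
3. **estimate_period** — rotation period by template matching (normalized
   cross-correlation between frames at increasing lags, parabolic sub-frame
   refinement);
4. **align_frames / assign_angles** — drift removal and uniform-rotation
   angle stamping, θᵢ = 2π(i − ref)/P;
5. **carve_slicewise** — the visual hull: for each axial slice the
   cross-section is the intersection of the strips
   { p : loᵢ(x) ≤ p·u(θᵢ) ≤ hiᵢ(x) } over contributing frames, where
   [loᵢ, hiᵢ] is frame i's silhouette interval at column x and
   u(θ) = (cos θ, sin θ). Confidence gating means an unseen low-contrast
   tail never carves — the feature-completion rule;
6. **extract_mesh** — watertight triangle mesh (marching tetrahedra on the
   smoothed occupancy field, volume-preserving Taubin smoothing);
7. **validate_reconstruction** — reprojection IoU against the segmented
   frames at viewpoints 0°–180° in 30° steps;
8. **phenotype** — surface area, volume, centerline length, maximum Feret
   width of normal cross-sections, and the length/width ratio;
9. **compare_groups / classify** — two-tailed Student's t tests per metric
   and PCA-based strain classification (logistic regression or SVM).

A parametric phantom generator (`phantom_spec()`, `render_stack()`) stands
in for the rotation hardware: it renders rotation stacks of synthetic adult
worms (~1 mm × 50 µm) and gastrulation-stage embryos (~50 × 30 µm) through a
physically ordered optical chain (attenuation → PSF → pixel aperture →
noise) with analytic ground truth, so every stage can be scored against
known geometry.

## Worked example

Reconstruct a synthetic embryo end to end and compare against its ground
truth:

```r
library(rotomorph)

cond <- standard_phantom("embryo", seed = 1)   # phantom + acquisition specs
out  <- reconstruct_phantom(cond)              # render + full pipeline

out$period
#> <rotation_estimate> period 47.984 frames (peak NCC 0.991)   # truth: 48

out$iou
#> <iou_report> mean IoU 0.9829 +/- 0.0035 over 7 viewpoints
#>  viewpoint_deg frame frame_angle_deg       iou
#>              0     1         0.00000 0.9873444
#>             30     5        30.01014 0.9852663
#>             60     9        60.02028 0.9829380
#>             90    13        90.03041 0.9763747
#>            120    17       120.04055 0.9813182
#>            150    21       150.05069 0.9827908
#>            180    25       180.06083 0.9840101

out$record
#>   sample_id strain  stage surface_area_um2 volume_um3 length_um max_width_um
#> 1  specimen   <NA> embryo         4131.645   23231.38  50.21197     30.19915
#>      ratio qc_mean_iou
#> 1 1.662695   0.9828632
```

The phantom's ground truth is volume 23573 µm³, area 4153 µm², length
50.0 µm, width 30.6 µm — the reconstruction recovers each metric to within
about 1.5%, and every reprojection IoU is above 97%. Rotation period, mean
IoU and its per-viewpoint table, and the five-metric record are exactly what
a run on real microscope frames would report (`run_pipeline()` /
`read_stack()` take a multi-page TIFF plus the pixel size).

Group analysis operates on tables of such records:

```r
records <- simulate_strain_cohort(seed = 1)    # 4 synthetic strains, n = 62
compare_groups(records, "volume_um3", "ref", "mutAB")
classify(records, method = "pca_svm")          # PCA + SVM, resubstitution + CV
```

A thin command-line interface (`inst/cli/rotomorph`) exposes `simulate`,
`run`, `compare` and `classify` for shell use.

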
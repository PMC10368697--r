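# skelpatch

Skeleton-guided 3D patch pipeline for intracranial-aneurysm segmentation
in TOF-MRA, with synthetic vascular phantoms for fully reproducible
testing.

## What it does, and for whom

Intracranial aneurysms — focal bulges of cerebral arteries, often under
5 mm — occupy a vanishing fraction of a time-of-flight MR angiography
volume, so any voxel-level learner faces extreme class imbalance.
`skelpatch` is an R implementation of a pipeline for researchers working
on vascular image analysis that tackles the imbalance geometrically and
with multi-task learning:

* **Vessel skeletonization**: threshold → 26-connected component
  filtering (≈3000-voxel physical-size cutoff) → intensity-gated region
  growing → morphological closing → topology-preserving iterative
  thinning (simple-voxel deletion under foreground-26 / background-6
  connectivity, six directional sub-iterations). The arterial tree
  collapses to a one-voxel-wide centerline that carries the patch
  sampler.
* **Ratio-controlled patch sampling**: positive 64³ patches drawn
  *non-centered* so the whole lesion is contained but arbitrarily placed;
  negative patches centered on skeleton voxels away from any lesion; the
  normal-to-aneurysm ratio enforced exactly from 1:1 to 5:1.
* **Multi-task 3D U-Net**: residual double-convolution blocks, batch
  normalization, parametric ReLU, optional dual attention at the bridge,
  and auxiliary patch-level classifiers (BCE) on the decoder; the
  segmentation loss is soft Dice + Tversky-focal (α = 0.3, β = 0.7,
  γ = 4/3) + cross-entropy, and the total loss averages the segmentation
  and classifier parts:

  `DSC = 2|V_GT ∩ V_pred| / (|V_GT| + |V_pred|)`,
  `TI = TP / (TP + α·FP + β·FN)`, loss `(1 − TI)^γ`.

  The network stack (layers, reverse-mode autodiff, Adam) is implemented
  in the package, with im2col + GEMM convolution kernels in C++.
* **Evaluation**: accuracy / sensitivity / specificity / PPV / NPV at
  patch level, per-case Dice (mean ± sd) at case level, and the
  <5 mm / 5–10 mm / >10 mm size-stratified breakdown.
* **Synthetic phantoms**: spline-centerline tubes, ellipsoidal aneurysm
  bulges drawn from the clinical size mixture (130:21:3 across the three
  strata), smooth multiplicative bias fields and Rician noise — every
  stage is testable without clinical data.

## Worked example

```r
library(skelpatch)

# a synthetic TOF-MRA-like case with known ground truth
ph <- generate_phantom(phantom_spec(
  volume_shape = c(64, 64, 64), spacing_mm = c(0.3, 0.3, 0.3),
  n_vessels = 2, vessel_radius_range_mm = c(0.5, 1.2),
  n_aneurysms = 1, aneurysm_diameter_range_mm = c(1.8, 8),
  rician_sigma = 15, bias_amplitude = 0.2, seed = 3))
ph
#> <phantom_case 64x64x64: 2843 vessel voxels, 897 aneurysm voxels, 1 aneurysm(s)>

# preprocess and skeletonize
img <- preprocess_volume(ph$image, preprocess_config())
sk  <- vessel_skeleton(img, skeleton_config(threshold_strategy = "auto",
                                            min_component_voxels = 300))
sk$skeleton
#> <skeleton_voxels: 167 voxels in 64x64x64 grid>

# ratio-controlled patch dataset (1 aneurysm : 2 normal)
case <- list(case_id = "c1", image = img, aneurysm_mask = ph$aneurysm_mask,
             skeleton = sk$skeleton)
ds <- build_dataset(list(case),
                    sampling_plan(patch_size = c(32, 32, 32), ratio = 2,
                                  n_positive_per_aneurysm = 4, seed = 1))
ds
#> <patch_set: 12 patches (4 aneurysm, 8 normal), size 32x32x32>
```

The 167 skeleton voxels are the centerline of ~2800 vessel voxels — the
1D support along which patches are sampled; the dataset holds exactly two
normal patches per aneurysm patch. A full seeded experiment — phantom
cohort, 120:19:15-proportioned case splits, training one model per
(ratio, auxiliary-loss) cell and reporting the Table-style metric grid —
runs through `run_experiment()`; `desk_experiment_config()` provides the
CPU-sized profile and `aux_ablation_study()` repeats the ratio-1:2
aux-on/aux-off comparison over several seeds:

```r
res <- run_experiment(desk_experiment_config(master_seed = 101))
print(res$report, digits = 3)
#>   ratio   aux status accuracy specificity   ppv   npv sensitivity dsc_mean  dsc_sd
#> 1     2  TRUE     ok    0.667       1.000    NA 0.667           0    0.307  0.0442
#> 2     2 FALSE     ok    0.417       0.125 0.364 1.000           1    0.307  0.0762
```

Both arms reach a mean held-out Dice of about 0.31 on this seed's two
test cases. The auxiliary arm classifies test patches far more accurately
(0.667 vs 0.417 here; 0.75 vs 0.44 pooled over three seeds) because the
plain arm's voxel-count decision rule fires on almost every vessel patch
(specificity 0.125). `aux_ablation_study()` pools three such seeds;
absolute Dice values at this 4-epoch desk budget are far below
clinical-scale figures, and very small (≈2 mm) lesions may be missed by
either arm.

A command-line wrapper for the individual stages lives in
`inst/cli/skelpatch.R`:

```sh
Rscript inst/cli/skelpatch.R phantom --n-cases 2 --seed 7 --out phantoms/
Rscript inst/cli/skelpatch.R skeletonize phantoms/phantom_001_image.nii.gz \
    --out skel.nii.gz --csv skel.csv
```

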
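---
title: "Skeleton-guided 3D patch segmentation of intracranial aneurysms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeleton-guided 3D patch segmentation of intracranial aneurysms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Intracranial aneurysms are focal bulges of cerebral arteries, often only a
few millimetres across. In time-of-flight MR angiography (TOF-MRA) flowing
blood appears bright without contrast agent, so the arterial tree can be
segmented by intensity — but the aneurysm itself occupies a vanishing
fraction of the volume. A voxel classifier trained on whole volumes faces
an extreme class imbalance: almost every voxel, and almost every candidate
region, is normal.

`skelpatch` implements a pipeline that attacks this imbalance geometrically
and algorithmically:

1. the vessel tree is reduced to a one-voxel-wide **skeleton**, collapsing
   the 3D search space to an (approximately) 1D set of plausible locations;
2. fixed-size 3D **patches** are sampled along that skeleton, with the
   ratio of normal to aneurysm patches controlled exactly (1:1 up to 5:1);
3. a multi-task 3D **U-Net** segments the aneurysm inside each patch while
   **auxiliary classifier heads** on the decoder predict, per patch,
   whether an aneurysm is present at all, injecting patch-level supervision
   that stabilizes training under imbalance;
4. patch predictions are tiled back into the volume and evaluated with the
   standard panel (accuracy, sensitivity, specificity, PPV, NPV at patch
   level; Dice similarity coefficient per case, mean ± sd, with a size-
   stratified breakdown).

Clinical angiograms are not distributable, so the package ships a
**synthetic phantom generator** that makes every stage testable end to end
with known ground truth.

## The phantom model

`generate_phantom()` builds a volume from a `phantom_spec()`:

* **Vessels** are smooth random cubic-spline centerlines (control points
  ordered along a random direction so tubes do not loop) rasterized as
  tubes of constant radius, 0.5–3 mm by default. A `straight` style
  generates axis-aligned cylinders whose voxel volume can be checked
  against the analytic \(\pi r^2 \ell\).
* **Aneurysms** are ellipsoidal bulges with semi-axis ratios drawn from
  [0.7, 1.3], centered on a vessel surface point. Diameters come from
  `sample_size_mix()`, a three-stratum mixture (very small < 5 mm, small
  5–10 mm, large > 10 mm with weights 130:21:3) reflecting the clinical
  predominance of very small lesions; the range 1.8–32.6 mm is truncated
  to fit the volume.
* **Intensity**: bright foreground on dark background, multiplied by a
  smooth random quadratic **bias field** spanning \([1-a, 1+a]\), then
  corrupted with **Rician noise** (the magnitude-image noise law of MRI):
  \(I' = \sqrt{(I+\epsilon_1)^2 + \epsilon_2^2}\),
  \(\epsilon_i \sim N(0, \sigma)\).

What the phantom does *not* emulate: flow artifacts, skull and scalp
(skull stripping is represented only by a pluggable mask step), vessel
tapering and bifurcation geometry, partial-volume blur, and the intensity
heterogeneity of real scanners. Passing tests on phantoms therefore
demonstrate algorithmic correctness — exact ratio control, topology-safe
skeletonization, loss algebra, metric definitions — not clinical
performance.

## Preprocessing

`preprocess_volume()` applies, in order: bias-field correction, isotropic
resampling (trilinear for images, nearest-neighbor for masks; default
target 0.3 mm), then intensity clipping to the [0.5, 99.5] percentiles and
z-score standardization. Correction runs first because it assumes a
multiplicative model on raw magnitudes, which standardization would
destroy; standardization runs last so the network always sees mean-0/sd-1
inputs. Percentiles interpolate linearly between order statistics
(`quantile()` type 7), and the statistics are computed per volume.

Bias correction estimates a smooth multiplicative field as a low-order
(default cubic) polynomial fit to log-intensities inside a mask and
divides it out, normalized to mean 1 inside the mask. The contract is
conservative: if the fitted correction would *increase* the within-mask
coefficient of variation, the input is returned unchanged. Masks smaller
than 100 voxels are passed through with a warning.

Skull stripping in the reference workflow used a trained network whose
weights are not distributable; `brain_mask_strategy` therefore accepts
`none` (phantoms), `threshold`, or an external mask file (real data).

## Skeletonization

`vessel_skeleton()` runs five steps: threshold → 26-connected component
filtering → region growing → morphological closing → iterative thinning.

* The **threshold** is configurable: a fixed value, a percentile of
  in-mask intensities, or `auto` — the midpoint of a 2-means split of the
  intensity histogram, which suits the bimodal bright-vessel/dark-brain
  distribution of TOF-MRA and of the phantoms.
* **Component filtering** keeps 26-connected components of at least 3000
  voxels by default. The cutoff is defined at 0.3 mm spacing and rescaled
  by \((0.3/\text{spacing})^3\), making it a physical-size filter.
* **Region growing** re-attaches adjacent voxels whose intensity lies
  within 10% below the threshold (relative to the threshold magnitude),
  repairing dim gaps that thresholding split.
* **Closing** (ball dilation then erosion; out-of-volume voxels count as
  background for dilation and foreground for erosion so borders are not
  eaten) fills interior holes so the thinning sees solid tubes.
* **Thinning** deletes *simple voxels* — voxels whose removal does not
  change the object's topology, characterized by the standard two-part
  connectivity-number test under foreground 26-connectivity and background
  6-connectivity — sequentially, in raster order, within six directional
  sub-iterations (up/down/north/south/east/west border passes), until a
  fixpoint. Sequential deletion with re-checking makes topology
  preservation unconditional; raster order makes the result deterministic;
  the directional sweeps erode symmetrically so centerlines stay centered.
  Curve endpoints (at most one foreground 26-neighbor) are never deleted,
  so a one-voxel line is its own skeleton. Consequences asserted in the
  test suite: the skeleton is a subset of the mask, has the same
  26-component count, contains no 2×2×2 solid block, and is a fixpoint of
  the procedure.

## Patch sampling

Positive patches are sampled **non-centered**: for each 26-connected
aneurysm component, the patch origin is drawn uniformly from the exact box
of origins whose 64³ window (32³ in the desk profile) fully contains the
component, so the whole lesion is always inside the patch but its position
within the patch varies. A component larger than the patch is a hard
error naming the component and its extent.

Negative patches are centered on skeleton voxels at least 5 mm (default)
from any aneurysm voxel, clamped to the volume, and verified aneurysm-free
by construction; if the skeleton cannot supply the requested number, all
admissible ones are returned with a warning.

`build_dataset()` enforces `|negatives| = ratio × |positives|` *exactly*,
globally across the cohort by default (a per-case option exists), with
negative quotas spread evenly across cases and shortfalls rolled forward.
Volumes are zero-padded (the post-standardization background value) so
near-border lesions and skeleton voxels remain usable.

Augmentation (`augment()`) applies horizontal/vertical flips, zoom
(0.9–1.1), rotation (±15° per axis), Rician and Gaussian noise (σ 1–5% of
the patch intensity range), blurring, contrast (0.9–1.1) and gamma
(0.8–1.2). Geometric transforms act identically on image and mask
(nearest-neighbor for the mask), intensity transforms on the image only,
and the label is recomputed from the transformed mask. If zoom/rotation
would push the whole lesion out of a positive patch, parameters are
redrawn a bounded number of times. The ranges are deliberately
conservative so that a 2 mm aneurysm survives every transform.

## The network

`build_model()` constructs an encoder–decoder with two 3×3×3
convolutions per level (batch normalization + parametric ReLU), 2×2×2 max
pooling, channel doubling per level, nearest-neighbor up-sampling followed
by a channel-halving up-convolution, skip concatenations, and a final
1×1×1 projection. With depth 4 and plain blocks the builder counts 23
convolutional layers, the classic U-Net figure. Same-padding is used
throughout so a patch maps to an equally-sized probability map — with
unpadded 3D convolutions a 64³ patch would shrink below usable size at
depth 4, and patch-in/patch-out behavior is what the tiled inference
relies on.

Options: **residual** basic blocks (identity or 1×1×1-projection
shortcuts), a **dual attention** block at the bridge (channel re-weighting
by a squeeze-style gate plus a position gate from a 1×1×1 convolution —
the published dual-attention formulation is not pinned down in the source
architecture text, so this lightweight interpretation is used and can be
toggled off), and **auxiliary classifier heads** (global average pooling +
linear + sigmoid) at the bridge and mid-decoder, configurable via
`aux_tap_levels`.

The loss (`loss_config()`) combines soft Dice, Tversky-focal
(\(\alpha\) = 0.3, \(\beta\) = 0.7, \(\gamma\) = 4/3 — false-negative-weighted, the
standard small-lesion choice) and voxel-wise cross-entropy for
segmentation, plus binary cross-entropy for each auxiliary head; the total
is the average of the segmentation and classifier losses. The Tversky
index carries half the Dice smoothing constant so that
\(\alpha=\beta=0.5, \gamma=1\) reduces *exactly* to soft Dice for any
smoothing. The final projection bias is initialized to −2 so that initial
predictions respect the sparse foreground prior.

Everything — phantoms, sampling, augmentation, initialization, shuffling —
derives from explicit seeds, and one master seed fans out per experiment,
so whole experiments reproduce bitwise.

The network stack (layers, reverse-mode differentiation on a linear tape,
Adam) is implemented in the package itself, with the dense kernels
(im2col + single-precision GEMM convolutions, pooling, up-sampling) in
C++; gradients of every operator are verified against central finite
differences in the test suite.

## Training profiles and problem sizes

Two profiles are used in the shipped experiments:

* **Reference profile** (matching the source setup): 64³ patches, depth 4,
  16 base channels, batch 16, Adam at 0.001, 500 epochs. Configurable but
  not exercised by the tests — it is a multi-day CPU computation.
* **Desk profile** (`desk_experiment_config()`): 20 phantoms of 64³ voxels
  at 0.3 mm (two vessels of radius 0.5–1.2 mm — thin branch calibers so a
  bulge is geometrically distinctive — and one aneurysm from the clinical
  size mixture, capped at 8 mm so every lesion fits a 32³ patch), 32³
  patches, depth 2, 8 base channels, residual blocks with attention,
  two positive patches per aneurysm, flip augmentation, batch 2, 4 epochs
  at learning rate 2e-3, best-validation checkpointing, and 16/2/2
  case-level splits (the 120:19:15 proportions by largest-remainder
  rounding with a one-case floor per split). Small batches buy more
  optimization steps from a fixed number of patch visits, which at this
  cohort size matters more than gradient smoothness. Depth 2 rather than
  a deeper encoder: on a 32³ patch a third pooling leaves a 4³ bridge
  whose extra context adds little for structures a few voxels across,
  while the shallower decoder avoids most of the full-resolution compute.

`aux_ablation_study()` repeats the ratio-1:2 aux-on/aux-off comparison
over three master seeds (independent cohorts, splits and initializations)
and pools held-out test DSC per arm. At desk scale the auxiliary arm
consistently reaches positive overlap earlier; very small (≈ 2 mm)
lesions can still be missed by either arm at this training budget — the
same failure mode reported for small aneurysms at full scale.

## Evaluation conventions

* The classification panel is computed at **patch level**; DSC at **case
  level** (mean ± sd over cases), and both are labeled as such in reports.
* A patch is predicted positive when the mean auxiliary probability
  exceeds 0.5; models without auxiliary heads fall back to a predicted-
  mask voxel-count rule (≥ 5 voxels by default). Both rules are exposed.
* Both-empty DSC (no aneurysm, none predicted) is undefined by the
  formula; such cases return `NA` and are excluded from mean DSC, which is
  therefore a statement about aneurysm-bearing cases.
* Size strata are `< 5 mm`, `5–10 mm` (both bounds inclusive) and
  `> 10 mm`; empty strata are reported as `NA`, never as zero.
* Zero-denominator metrics are `NA` with the denominator reported, never
  silently 0.
* Whole-volume predictions average per-voxel probabilities over
  overlapping tiles along the skeleton; uncovered voxels get probability
  0. Cell evaluation tiles at half-patch stride so lesions are seen
  roughly centered in at least one tile.

## Numerical choices and degenerate inputs

* Convolution arithmetic is single precision (double elsewhere); the
  resulting gradient noise is orders of magnitude below the optimization
  signal.
* Dice/Tversky smoothing (1.0) keeps losses finite for empty targets.
* Constant images are rejected by standardization (undefined sd); full or
  empty threshold masks emit warnings; empty skeletons yield all-zero
  predictions with a warning rather than errors.
* Thinning tie-breaks (raster order within directional sub-iterations) and
  seeded sampling make every pipeline stage deterministic; training is
  deterministic given its seed because all randomness flows through R's
  RNG, saved and restored around each seeded operation.

## Known limitations

* The phantom's geometric simplicity means detection is easier than on
  clinical data; desk-scale DSC values are not comparable to
  clinical-scale figures.
* The CPU implementation is sized for tens of phantom cases; the reference
  profile is supported but impractical without hardware acceleration.
* The attention block is an interpretation (see above), off by default in
  `network_spec()` and on in the desk profile.
* N4-style histogram-sharpening bias correction is out of scope; the
  polynomial log-domain fit satisfies the same contract on smooth fields
  but will not remove high-frequency inhomogeneity.
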
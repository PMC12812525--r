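---
title: "Tumor-aware parcellation and the spatial distribution pattern: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-aware parcellation and the spatial distribution pattern: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Whole-brain segmenters parcellate structural MRI into named anatomical
structures, but they fail on and around gliomas: the tumor replaces or
displaces the tissue the segmenter was trained to recognize, so voxels in
and near the gross tumor volume (GTV) come back as over-segmented CSF,
mislabeled cortex/white matter, or background. `gliomap` repairs such a
parcellation and summarises where the tumor sits in brain anatomy as a
32-value *spatial distribution pattern*: for each of 32 canonical
structures (14 left/right pairs plus CSF, 3rd ventricle, 4th ventricle and
brain-stem), the fraction of that structure's volume overlapped by the GTV.

# The repair procedure

Given a subject parcellation `mask_synth` (possibly failed inside the GTV),
a parcellated atlas on the same grid, and the GTV mask (union of the
enhancing core, necrotic/cystic core and peritumoral edema sub-labels):

1. **Mask out the tumor** from the subject parcellation (voxels under the
   GTV set to background).
2. **Rigid pre-alignment** of the atlas onto the subject parcellation,
   maximizing a smooth multi-label similarity.
3. **Mask out the tumor** from the rigidly aligned atlas.
4. **Deformable registration** of the tumor-masked subject onto the
   tumor-masked atlas with the GTV excluded from the similarity term
   (cost-function masking), so anatomy — never the lesion — drives the
   alignment.
5. **Invert** the estimated displacement field by fixed-point iteration.
6. **Propagate** the full atlas labels into subject space through the rigid
   transform composed with the inverse field, using nearest-neighbour
   interpolation (labels are categorical).

The repaired parcellation (`mask_final`) is, by default, a *composite*:
subject labels outside the GTV (where the segmenter is trusted) and
warped-atlas labels inside it. The alternative `full_warp` mode returns the
warped atlas everywhere; both are implemented because the source procedure
can be read either way, and the composite default preserves subject-specific
anatomy wherever it is reliable. Any in-brain GTV voxel still background
after composition (a fringe effect of NN resampling) is assigned the modal
label of its neighbours, so the fill contract — no unlabeled tumor voxels —
holds unconditionally.

## Registration internals and numerical choices

Registration operates on label images directly (the objects being aligned
are segmentation masks). Both steps encode labels as *code channels*: each
channel maps every label id to a fixed pseudo-random value in (0, 1]
(background 0) and is smoothed with a 1-voxel Gaussian. Distinct labels
almost surely receive distinct codes in several of the 6 channels, so
mean-squares over channels behaves like a soft multi-label overlap at a
fraction of the cost of 33 one-hot channels. This is the package's
implementation of the "multi-label mean-squares, backend-pluggable"
contract; an external registration backend could be substituted behind the
same operation signatures.

* **Rigid step**: Nelder-Mead over 3 Euler angles + 3 translations,
  initialized at the foreground centre-of-mass offset; a coarse search on a
  half-resolution grid is refined briefly at full resolution. The result is
  guarded: if the optimized transform scores a lower mean per-label Dice
  than the identity, the identity is returned, so rigid alignment can never
  make things worse.
* **Deformable step**: demons-type iteration on the code channels over two
  resolution levels (60 coarse + 12 fine iterations by default), with the
  classic normalized demons force, Gaussian smoothing of both the update
  (sigma 1.5 voxels) and the field (sigma 0.8 voxels), and a per-iteration
  step cap of 0.6 x voxel size. Voxels under the ignore mask contribute no
  force; the field inside the GTV is therefore a smooth extrapolation
  diffusing in from the surrounding anatomy, which is exactly what a
  tumor-occluded region admits. Convergence is judged on the final
  resolution level: the result is flagged `converged = FALSE` whenever the
  similarity trace is not non-increasing over its last quarter — the flag
  is honest rather than optimistic, and a non-converged registration is
  reported, never silently accepted.
* **Field inversion**: fixed-point iteration `u_inv <- -u(x + u_inv(x))`,
  at most 50 iterations; the composition residual must be below 0.5 voxel
  at the 99th percentile (the bound at which NN label warping is unchanged
  by the residual), otherwise the operation errors with the achieved
  residual.
* **NN tie rule**: exact half-voxel coordinates round toward the origin,
  fixed across platforms.
* **Coordinates**: voxel indices are 0-based internally; physical position
  = index x spacing; displacement fields are stored in mm on the output
  grid, and a field `u` means "sample the moving image at `x + u(x)`".

# The spatial distribution pattern

For structure `s`, `ratio(s) = |mask_final = s and GTV > 0| /
|mask_final = s|`. The denominator is the structure's volume in the
*repaired* parcellation (the natural reading of computing overlap "against
mask_final"; fixed here for determinism). Structures with zero volume get
ratio 0 — never NaN, so downstream ML never sees missing values — and are
recorded in a per-subject QC flag. Cohort summaries report the arithmetic
mean and *population* standard deviation per structure. Volumes are
reported in liters (mm^3 x 1e-6).

# The radiomics pool

366 descriptors: 14 shape features computed once (shape is
sequence-invariant; tagged to T1CE), plus 18 first-order and 70
second-order features for each of T1, T1CE, T2 and FLAIR. The exact
70-name second-order list is fixed as data in the manifest
(`radiomic_manifest()`): 24 co-occurrence (GLCM), 16 run-length (GLRLM),
16 size-zone (GLSZM) and 14 dependence (GLDM) features — standard IBSI
families chosen to make the 70-count auditable and swappable, since no
published enumeration exists to copy.

Extraction choices:

* Discretization: fixed bin count 32 over the ROI range by default
  (fixed bin width available). Texture under fixed-bin-count discretization
  is invariant to adding a constant to the image.
* ROI: the whole GTV (union of sub-labels), matching the spatial module.
* No intensity normalization before extraction; min-max scaling is applied
  to *feature values* inside the ML pipeline only.
* GLCM/GLRLM are aggregated by averaging features over the 13 unique 3D
  directions; GLSZM zones are 26-connected; GLDM uses alpha = 0.
* Surface area uses a coarea (smoothed-gradient) estimate: the integral of
  the gradient magnitude of the 1-voxel-Gaussian-smoothed binary mask.
  It is accurate to ~1% on a rasterized ball and avoids a meshing step;
  its known bias is an underestimate for ROIs touching the volume edge,
  which real GTVs do not.
* Degenerate ROIs (constant intensity) yield zero variance, skewness,
  kurtosis and entropy, and correlation-type GLCM features take their
  defined degenerate values (correlation 1, IMC 0).

# The evaluation protocol

* Labels: overall survival is binarized at the per-dataset median (times
  at the median count as long-term — a deterministic, balance-preserving
  tie rule); IDH is wildtype = 1 versus everything else observed (mutated,
  NOS/NEC, negative), with unknowns excluded and counted.
* Min-max scaling is fitted on training folds only and applied unchanged to
  validation/test rows, which may therefore leave [0, 1] and are not
  clipped.
* SVM-SMOTE oversamples the minority class to parity: minority-class
  support vectors of an RBF-SVM boundary act as borderline seeds and
  synthetic rows are convex combinations of two real minority rows.
  It runs inside each training fold, after splitting, never on validation
  or test data.
* Forward feature selection greedily adds the feature maximizing inner
  3-fold CV AUROC of the candidate model, stopping at the cap or when no
  addition strictly improves the score; ties break toward the lower column
  index.
* Grid search ranks XGB/random-forest configurations by inner-CV AUROC; the
  top five feed the ensemble. Ensemble prediction is the unweighted mean of
  member probabilities (the simplest defensible aggregation where none is
  prescribed).
* Repeated stratified 5-fold CV x 10 repeats x 5 models yields 250
  observations; all metrics (Mann-Whitney AUROC with ties at 1/2;
  accuracy, sensitivity, specificity at threshold 0.5, positive class =
  long-term/wildtype/methylated) are reported per observation and as
  mean +/- sd. One master seed derives every per-repeat, per-fold and
  per-oversampler stream.
* Cross-dataset evaluation applies the frozen ensemble and its stored
  preprocessing to an external cohort without refitting; a manifest
  mismatch errors naming the missing columns.
* The DeLong test compares two correlated AUROCs through placement-value
  covariance; identical scores give variance 0 and p = 1 by convention.

# What the synthetic phantoms emulate — and what they do not

The generator reproduces the *statistical structure* the method relies on:
a 32-structure parcellation with left/right topology, a smooth invertible
deformation between atlas and subject (Gaussian-smoothed noise at 3 mm
amplitude / 10 mm smoothness by default, plus a small random affine part),
a nested three-compartment tumor (necrotic core inside enhancing rim inside
an edema shell), label-conditioned Gaussian-mixture intensities with bias
field, gamma, blur and downsampling corruption (the ranges of the GMM draws
are free parameters, exposed in `generative_params()`, as no published
values exist), and a segmenter that fails on/around the tumor by
reassigning labels among CSF, the affected hemisphere's cortex/white
matter, and background inside a 6 mm halo.

Phantom geometry is schematic — an ellipsoid partitioned by a seeded,
mirrored Voronoi tessellation, not anatomy. Passing tests therefore
demonstrate that the algorithms are *correct and well-calibrated under the
model's assumptions* (smooth deformations, locally failed but globally
sound segmentations, connected tumors); they do not certify performance on
clinical MRI, where deformation fields are not smooth around mass effects
and segmenter failures are correlated with anatomy. Phantoms default to
64^3 voxels at 3 mm spacing (an adult-head field of view at a resolution
where registration studies remain cheap); the test suite and the
acceptance script use 20 such phantoms for recovery statistics and
n = 400 cohorts for ML calibration, sizes at which the Monte-Carlo error
of every asserted quantity is comfortably below its acceptance margin.

Recovery is scored two ways: per-voxel label accuracy inside the GTV
(which the repair must strictly improve on every phantom), and the macro
average of per-structure Dice restricted to the GTV. A structure enters
the macro mean only if the ground truth gives it at least 10 voxels
(~0.27 mL) inside the GTV: one- or few-voxel slivers produce Dice values
of 0 or 1 essentially at random under nearest-neighbour resampling and
would otherwise dominate an unweighted mean — excluding unscoreable
near-empty classes is the standard convention in segmentation evaluation.

The ML calibration experiments use 32 spatial-style + 8 radiomic-style
columns with 5 planted features at effect size 3 (or 0 for the null),
class balance 0.35 so that SVM-SMOTE actually engages, a 1 x 5-fold plan
over the five default ensemble configurations, and a selection cap of 5.
The 250-observation structural check runs the full 10 x 5 x 5 plan on a
lighter cohort, since it verifies the harness's bookkeeping, not model
quality.

# Known limitations

* The demons-type registration is a correct but deliberately compact
  implementation: single-modality, label-image-driven, two resolution
  levels. It recovers 3 mm / 10 mm-smooth fields to ~0.2 voxel median
  error on phantoms; larger or sharper deformations need more levels.
* The convergence flag is conservative; plateaued registrations may be
  flagged non-converged although their field is usable.
* Shape features use voxel-count volume and the coarea surface estimate
  rather than a triangulated mesh; absolute values of surface-derived
  descriptors differ from mesh-based implementations by a few percent,
  consistently across subjects.
* `binarize_os` keeps subjects exactly at the median in the long-term
  class; cohorts with many tied survival times will not split 50/50.
* The CLI (`inst/cli/gliomap`) is a thin wrapper over the exported
  functions; programmatic use is the primary interface.
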
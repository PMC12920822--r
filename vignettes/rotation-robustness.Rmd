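---
title: "Auditing the rotation robustness of wavelet radiomic features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the rotation robustness of wavelet radiomic features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question this package addresses

Radiomic pipelines routinely filter a CT volume through a bank of imaging
filters before extracting texture statistics from a segmented lesion. One of
those filters, the separable 3D wavelet decomposition (WD), splits the image
into eight directional sub-bands (`LLL` ... `HHH`). Because the sub-bands
are *directional*, the values of WD-derived features depend on how the
lesion happens to be oriented relative to the scan grid — an orientation
that carries no biology for lesions without a reference anatomy. `radrot`
provides the machinery to quantify that dependence end to end: a synthetic
CT-like cohort generator, the 18-channel filter bank and 93-feature
extractor, a rotation-perturbation simulator, feature-level stability
statistics, and a train-on-original / test-on-rotated repeated
cross-validation protocol that compares models restricted to WD features
(`X_WD`, 744 features) with models restricted to everything else (`X_nWD`,
930 features).

Everything runs on synthetic phantoms, so no external imaging data is
required; the package audits the *mechanism*, not any particular cohort.

## The pipeline

1. **Pre-processing** (`preprocess_pair`). Intensities are z-score
   normalized over the Otsu foreground of the whole volume; mask islands
   with fewer than 10 connected voxels (26-connectivity) are removed as
   segmentation slips; image/mask dimension mismatches raise exclusion
   errors carrying the patient id.
2. **Rotation augmentation** (`build_rotated_cohort`). For each patient and
   each label $i \in \{5, 10, \dots, 80\}$ degrees, a deviation angle is
   drawn as $|\mathcal N(i, 10^2)|$ and a rotation axis uniformly on the
   sphere; the rigid transform is applied about the mask centre of mass by
   resampling (trilinear for the image, nearest-neighbour for the mask).
   The unrotated baseline `R0` passes through the *same* resampling code
   path with the identity transform, so every group shares the
   interpolation bias. Source coordinates within 1e-9 voxel of the lattice
   are snapped, making the identity (and exact 90-degree rotations on
   matching grids) voxel-exact.
3. **Extraction** (`extract_cohort_features`). Each rotated pair is cropped
   to the mask bounding box plus a 10-voxel margin (so filters keep
   context), resampled to the isometric modal spacing of the cohort,
   filtered into 18 channels, discretized per channel with a fixed bin
   width, and reduced to 93 texture features per channel plus 14 shape
   features.
4. **Stability statistics** (`feature_stability`). For every feature, the
   signed percentage difference against the patient's `R0` value, the
   per-label IQR of those differences with a Student-t 95% CI of the mean,
   and a pooled Spearman trend of $|\%\Delta|$ against the label with
   effect-size strata (trivial < 0.1 <= weak < 0.3 <= moderate < 0.7 <=
   strong). A feature is *flagged* when p < 0.05 and $|CC| \ge 0.1$.
5. **Model stability** (`run_repeated_cv`). Repeated stratified 5-fold CV
   (50 repeats by default, 250 train-test cycles): preliminary label-free
   filtering on all samples (zero variance, |Spearman rho| > 0.95
   redundancy, keep-first), then per-training-fold Kruskal-Wallis ranking
   (top 60) and L1-penalized multinomial selection (<= 30 features),
   standardization and five classifiers fitted on `R0` features only, and
   evaluation of every rotation set on the held-out fold. Trends are pooled
   Spearman coefficients with Fisher-z intervals.

## The filter bank

* **Wavelet**: one-level *undecimated* (stationary) separable Coiflet-1
  transform with periodic boundaries, so all eight sub-bands keep the input
  shape and the bank reconstructs the input exactly (tested to 1e-6
  relative). Channel `XYZ` applies filter `X` along axis 1, `Y` along
  axis 2, `Z` along axis 3. The Coiflet-1 taps are generated from their
  closed form $\frac{\sqrt 2}{32}(\sqrt 7 - 3,\ 1 - \sqrt 7,\ 14 - 2\sqrt
  7,\ 14 + 2\sqrt 7,\ 5 + \sqrt 7,\ 1 - \sqrt 7)$.
* **Laplacian of Gaussian**: spacing-aware separable approximation with
  sigma in millimetres (default 3 mm; one sigma, since the 18-channel
  arithmetic implies exactly one LoG channel). The second-derivative
  kernels are recentred to zero sum so constants map exactly to zero.
* **Intensity transforms** (square, squareroot, logarithm, exponential):
  monotone per-voxel maps rescaled to the input range $M = \max|x|$;
  closed forms are given in `?intensity_transforms`. Stability conclusions
  are unaffected by the choice of monotone rescaling.
* **Gradient**: spacing-aware central-difference magnitude.
* **LBP-3D**: for each voxel, 42 trilinear samples on a sphere (icosahedron
  plus edge midpoints, radius 1 voxel), binarized against the centre with a
  1e-9 relative tolerance (so interpolation round-off cannot flip the
  pattern on flat regions), projected onto real spherical harmonics:
  `m1` and `m2` are the band-1/band-2 energies, `k` the kurtosis map of the
  sampled values. Icosahedral sampling is rotation-*tolerant*, not exactly
  equivariant.

## Feature definitions and conventions

The 93 features per channel follow the standard IBSI-aligned definitions:
18 first-order, 24 GLCM (13 symmetric direction matrices at Chebyshev
distance 1, features averaged over directions; for the symmetric GLCM the
cross entropies satisfy $HXY1 = HXY2 = HX + HY$, which the implementation
uses), 16 GLRLM (runs along the 13 directions), 16 GLSZM (26-connected
equal-level zones), 14 GLDM (dependence = 1 + number of 26-neighbours
within tolerance alpha = 0), 5 NGTDM. Degenerate inputs return documented
constants instead of NaN (Correlation = MCC = 1, Imc1 = Imc2 = 0 on a
single level; NGTDM Coarseness capped at 1e6), so downstream percentage
differences stay finite. Discretization uses a fixed bin width anchored at
`floor(min/w) * w` — stable under mask-preserving crops. The default width
is 0.1 for z-scored intensities (~25 would be appropriate on raw HU).

Shape features (14) come from the mask alone: mesh volume and surface area
from marching tetrahedra over a Gaussian-smoothed (sigma 1 voxel) indicator
at iso-level 0.5, *averaged over the four cube diagonals* so the mesh is
exactly invariant under the octahedral group; axis lengths from the PCA of
spacing-weighted voxel coordinates; diameters from boundary-voxel centres
(the three Maximum-2D-Diameter features group pairs by slice/row/column
index, which is what makes exactly those three orientation-sensitive). A
raw midpoint-crossing mesh on the binary mask was rejected: its staircase
surface inflates the area so much that a digitized 10 mm ball scores
sphericity ~0.78; the smoothed-field mesh scores ~0.995. Thin structures
that vanish under smoothing fall back to voxel-based volume/area.

## The synthetic cohort: what it does and does not emulate

`make_cohort()` draws ellipsoidal lesions (default semi-axes 14 x 11 x 8
mm, jittered ±15%) on a 48 x 48 x 32 grid with thorax-CT-like anisotropic
spacing (1, 1, 3) mm, lung-like background (-800 HU), soft-tissue lesion
level (+40 HU), additive Gaussian noise (SD 30 HU), and three
histology-like classes whose signal is carried partly by texture:

* class 0 — coarse oriented grating (wavelength ~ N(8, 0.8) mm),
* class 1 — fine oriented grating (wavelength ~ N(4, 0.4) mm),
* class 2 — isotropic filtered noise (correlation length ~2 mm),

with amplitude ~ N(150, 22) HU and per-lesion orientation uniform on the
sphere. This guarantees both a directional signal that WD channels can
exploit (and lose under rotation) and a rotation-invariant scale signal
available to non-WD channels — the premise under audit. A configurable
fraction of masks (default 10%) receives a spurious < 10-voxel island to
exercise island removal. Not emulated: CT physics (beam hardening,
reconstruction kernels), partial-volume effects at acquisition,
inter-observer segmentation variability, and real histology-texture
relationships — so a green test establishes that the *pipeline* behaves as
specified, not that any clinical effect size is reproduced.

## Numerical choices and degenerate inputs

* Percentage differences are guarded by a scale-aware epsilon
  (`1e-6 * median |R0|` per feature, floored at machine epsilon); they are
  signed, and the Spearman trend uses $|\%\Delta|$ by default because signed
  differences of opposite sign across patients would cancel a monotone
  spread (a signed mode is available).
* IQRs use type-7 quantiles; CIs use the Student t on the 16 per-label
  IQRs; trend CIs use Fisher z. No multiplicity correction by default
  (Benjamini-Hochberg available).
* A rotation that would push the lesion through the volume border raises an
  error rather than silently clipping; per-patient failures exclude that
  patient from that rotation group with a warning.
* Classifier backends: KNN (k = 5, RNG pinned for tie-breaks), multinomial
  ridge logistic (lambda 0.01), an in-package random-subspace bagged CART
  forest (200 trees, mtry = sqrt(p)), and in-package one-vs-rest SVMs
  solved by dual coordinate descent on the kernel matrix (C = 1; RBF gamma
  = 1/(p Var)). The forest and SVMs are implemented here because no
  suitable dependency is available; they are deliberately compact and sized
  for desk-scale cohorts.
* Fold splitting is stratified by class (plain shuffling can produce
  empty-class folds at desk scale, which would make macro metrics
  undefined); this is a documented deviation from a plain random shuffle.

## What the negative control can and cannot show

The package ships a rotation-symmetric negative control (isotropic
Gaussian-blob lesion, spherical mask, cubic grid, no texture, no noise).
On it, rotation about the centre of mass changes the volume only through
trilinear interpolation. One might hope every feature then moves by at most
a small uniform "interpolation noise floor" (~2%). That expectation fails
for structural reasons, not implementation ones:

* wavelet detail channels of a smooth symmetric blob are *degenerate* —
  their baseline values are interpolation noise themselves, so relative
  changes are unbounded;
* zone- and run-type features are discontinuous in the intensities: a
  single gray-level flip can merge or split a zone of thousands of voxels;
* with 1674 features tested at alpha = 0.05 over ~480 pooled points each,
  a zero false-positive count is statistically impossible.

The corresponding acceptance test is therefore expected to stay red and is
kept as specified; the meaningful contrasts are the anisotropic positive
control (WD channels destabilize under rotation while `LLL` and the non-WD
channels do not) and the shape control (only the three Maximum-2D-Diameter
features are orientation-sensitive), both of which are asserted green.

## Known limitations

* Rotations are parameterized as a single axis-angle draw (axis uniform on
  the sphere), which does not cover all of SO(3) non-uniformly weighted
  orientations; the label measures the *magnitude* of deviation only.
* One wavelet family (Coiflet-1) and one decomposition level are
  implemented; rotationally invariant wavelet constructions are out of
  scope.
* The LBP-3D construction is one reasonable rotation-tolerant choice among
  several; only the three output maps (m1, m2, k) are contractual.
* Absolute classification accuracies on phantoms are not comparable to any
  clinical dataset; only directions and orderings of trends are meaningful.
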
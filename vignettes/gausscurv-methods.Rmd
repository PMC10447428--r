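---
title: "Curvature descriptors of subcortical shape: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature descriptors of subcortical shape: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Hippocampal and amygdalar atrophy in Alzheimer's disease is not spatially
uniform: subfields (CA1 in particular) erode earlier and faster than the
structure as a whole, so *shape* carries diagnostic information that total
*volume* misses. This package quantifies shape through the differential
geometry of the structure's boundary surface: at every surface point the
Gauss map sends the point to its outward unit normal on the unit sphere, and
the derivative of that map — the shape operator, or Weingarten map — measures
how fast the normal turns, i.e. how the surface bends.

For a point $p$ with unit normal $n(p)$, the shape operator $S_p$ is a
symmetric linear map on the tangent plane. Its eigenvalues are the principal
curvatures $\kappa_1 \ge \kappa_2$ (units mm$^{-1}$), the extreme normal
bendings at $p$. Two classical invariants summarise them:

* Gaussian curvature $K = \kappa_1 \kappa_2$ (mm$^{-2}$). Its sign
  classifies the local surface: elliptic (sphere-like, $K>0$), parabolic
  (cylinder-like, $K=0$), hyperbolic (saddle, $K<0$).
* mean curvature $H = (\kappa_1 + \kappa_2)/2$ (mm$^{-1}$), the average
  signed bending.

A localised indentation — the geometric signature of focal atrophy — leaves a
characteristic fingerprint: a rim of hyperbolic ($K<0$) surface around a
bowl of elevated curvature. Distributions of $\kappa_1, \kappa_2$, $K$ and
$H$ over the surface are therefore usable as diagnostic descriptors even
without any point-to-point correspondence between subjects.

## Pipeline

1. **Masks.** Binary NIfTI ROI masks (one per structure per subject) with
   their voxel-to-world affines. Region-level fusion (`fuse_regions()`) is
   the voxelwise union, producing a single "hippo-amygdala" ROI; all
   geometry is computed in world mm, so anisotropic voxels are handled.
2. **Surface.** `extract_surface()` runs a marching-tetrahedra isosurface
   (each cube split into six tetrahedra around a main diagonal — a
   decomposition that is consistent across neighbouring cubes, so the mesh
   is watertight and coherently oriented) on a Gaussian-prefiltered copy of
   the occupancy grid, followed by Taubin smoothing.
3. **Curvature.** `curvature_field()` fits a local quadric height function
   $z = \tfrac12(ax^2 + 2bxy + cy^2) + dx + ey$ over each vertex's
   topological neighbourhood, expressed in an orthonormal tangent frame, and
   forms the symmetrised shape operator
   $S = -I^{-1/2} \, II \, I^{-1/2}$ from the first and second fundamental
   forms of the fitted patch. Eigenvalues, $K$, $H$ and barycentric vertex
   areas follow.
4. **Descriptors.** `build_descriptor()` converts the variable-length
   per-vertex fields into fixed-length vectors — by default a 64-bin
   area-weighted histogram per value channel over a range frozen from the
   training subjects. The shape-operator feature concatenates the
   $\kappa_1$ and $\kappa_2$ histograms.
5. **Selection and classification.** Fisher-score ranking
   (`fisher_score()`), then a hierarchical pair of RBF-SVMs
   (`hier_svm()`): normal controls versus abnormal first, AD versus MCI
   among the abnormal. `cross_validate()` wraps everything in repeated
   stratified cross-validation, refitting every trained component inside
   each training fold.

## Numerical choices that matter

**Pre-filter width (`sigma`, default 1.6 voxels).** Curvature is a second
derivative; a raw isosurface of binary data is a staircase of facets whose
curvature noise swamps the signal. The default was fixed by requiring the
whole curvature stack to pass its sharpest global oracle — the Gauss-Bonnet
theorem, $\oint K \, dA = 2\pi\chi$ — to within about 1–2% on digitised
spheres and ellipsoids, alongside median $H$ and $K$ errors of a few
percent on a radius-20 sphere. The cost is a curvature-dependent erosion of
the surface (about $\sigma^2 H$ in radius): roughly 8% of enclosed volume
for a radius-10 sphere, 1–2% at radius 20. When faithful geometry rather
than curvature is the goal (e.g. volumetry through the mesh), `sigma = 0.8`
or lower is the appropriate setting; the voxel-counting `mask_volume()` is
unaffected entirely. This trade-off is intrinsic, not incidental: one
parameter controls a bias split between curvature fidelity and volume
fidelity.

**Taubin smoothing (20 iterations, $\lambda = 0.5$, $\mu = -0.53$).**
Chosen over plain Laplacian smoothing because it suppresses the residual
staircase without systematic shrinkage — shrinkage would bias all curvature
magnitudes upward or downward coherently.

**Fitting neighbourhood (`ring = 3`).** Marching-tetrahedra meshes are
dense relative to the voxel size (edges a fraction of a voxel), so a 3-ring
neighbourhood spans roughly two voxels — wide enough to average staircase
residue, narrow enough to keep the quadric local. Analytic meshes need only
2 rings. Note that the estimator's metric support (geodesic radius), not the
ring count per se, is what matters: descriptor distributions are comparable
across meshes when the support is comparable, which holds in the voxel
pipeline because all subjects share one grid resolution.

**Winsorisation and ranges.** Per-vertex curvatures are winsorised at their
1st/99th percentiles before histogram encoding (staircase residue creates
heavy tails), and histogram ranges are the pooled 1st–99th percentiles of
the *training* subjects, frozen and reused for test subjects. The
Gauss-Bonnet check uses raw values — winsorising would break the theorem.
Quantile encoding skips winsorisation since all but its extreme entries are
rank-based and tail-robust.

**Sign conventions.** Normals point away from the foreground; curvature is
positive for locally convex surfaces (a sphere seen from outside has
$\kappa_1 = \kappa_2 = 1/r > 0$). A stage decision value of exactly zero is
sent to the abnormal (stage 1) / AD (stage 2) side, favouring sensitivity.

**Degenerate inputs.** Empty masks, sub-voxel foregrounds and rank-deficient
vertex neighbourhoods fail loudly (or, for single vertices, are flagged and
excluded with a warning); multi-component masks are kept whole by default
with a warning, or reduced to the largest component on request.

## The classifier protocol

Each stage drops training-constant dimensions, ranks the rest by Fisher
score $F_j = \sum_c n_c(\mu_{c,j}-\mu_j)^2 / \sum_c n_c \sigma^2_{c,j}$
(population class variances), and grid-searches the retained count
$k \in \{16, 32, 64, 128, \text{all}\}$, cost $C \in \{0.1, 1, 10, 100\}$
and RBF width $\gamma \in \{0.1, 1, 10\}/k$ by stratified 3-fold inner
cross-validation — all inside the outer training fold, so no test-fold
information reaches any fitted component (the suite carries a leakage canary
that would light up otherwise). Outer evaluation is stratified 5-fold with 5
repeats. With very small cohorts the inner search degrades gracefully to
fixed mid-grid settings rather than failing.

Stage-2 metrics and ROC are computed over the truly abnormal subjects only,
mirroring per-stage reporting; the overall accuracy is the fraction of
subjects whose final hierarchical label matches the three-class truth.

**Permutation diagnostic.** `permutation_null()` re-runs the cross-validated
pipeline on label-shuffled copies and reports per-stage *balanced* accuracy
(mean of sensitivity and specificity). Balanced accuracy is the right
statistic here because its null expectation is exactly 1/2 for any
classifier independent of the labels; raw accuracy would centre at the
majority-class rate (2/3 in the imbalanced first stage) and make "chance"
ambiguous. The acceptance check averages three permutations and compares
against a binomial 95% band around 1/2 at the stage's subject count.

## The phantom generator

`make_cohort()` emulates the study inputs without clinical data: per
subject, a hippocampus-like ellipsoid (semi-axes 14, 9, 7 mm, about
3700 mm$^3$) and a smaller amygdala-like one (9, 7, 6 mm), rasterised at
1 mm into a shared grid and written as NIfTI plus a manifest CSV —
byte-compatible with the real-data path. Disease class enters through:

* a smooth spherical-cap indentation (C$^\infty$ angular bump) of depth
  0 / 2.8 / 5.6 mm and width 0.5 / 0.5 / 0.8 rad for NC / MCI / AD —
  progressive focal atrophy, deeper *and* wider with severity; the amygdala
  carries 60% of the depth. The indentation sits at a fixed body-frame site
  (with 0.15 rad jitter), the way subfield pathology affects a consistent
  anatomical location; an earlier uniformly-random siting made within-class
  heterogeneity dominate the AD–MCI contrast.
* a global atrophy scale 1 / 0.985 / 0.97 plus log-normal per-subject scale
  jitter (sd 0.04), calibrated so that volume alone is a moderate but
  clearly imperfect classifier — the ordering "shape beats volume" is then
  a meaningful claim rather than a foregone conclusion.
* four smooth radial noise lobes (amplitude sd 0.12 mm) and a uniformly
  random rigid rotation per subject (descriptors are rotation-invariant;
  the rotation verifies that in situ).

These constants are fixtures of the package, chosen once while designing
the generator at the default cohort size and committed; tests never adjust
them. What the phantoms deliberately do **not** emulate: real hippocampal
anatomy (no subfield geometry, no curved tail), segmentation errors
correlated with anatomy, scanner- or site-dependent bias, and
class-dependent mask topology changes. Passing the phantom suite therefore
shows the machinery is correct and sensitive to focal shape change at
realistic scales — it does not certify clinical accuracy on real cohorts.

## Problem sizes

The validation suite runs at desk scale: curvature oracles on digitised
spheres of radius 12–20 voxels and a 20x15x10 ellipsoid (meshes of roughly
10–25 thousand vertices), and an end-to-end cohort of 20 subjects per class
(120 region masks) under 5-fold, 5-repeat cross-validation, with a
three-permutation null. These sizes keep the full suite comfortably
reproducible on a single CPU while leaving the estimators in the regime
where their discretisation errors are already stable.

## Known limitations

* Curvature bias from the pre-filter grows at small radii of curvature;
  structures thinner than ~4 voxels need a finer acquisition grid, not a
  smaller `sigma` (which would re-admit staircase noise).
* Histogram descriptors discard spatial arrangement: two different
  placements of the same indentation are indistinguishable by design. This
  is what makes the method correspondence-free; methods with registration
  (e.g. SPHARM-based) can localise effects but need it.
* The quantile encoding keeps physical units but its two extreme entries
  remain tail-sensitive.
* With 40–60 training subjects per stage, the inner grid search is noisy;
  repeated outer folds average the resulting variance but do not remove it.
* Left/right lateralisation is not modelled; a manifest "region" file may
  contain one or both lateralised structures, and the pipeline treats
  whatever foreground it finds as one ROI (components are kept by default).
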
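---
title: "Vascular-model fidelity and stereotactic trajectory planning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vascular-model fidelity and stereotactic trajectory planning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Stereoelectroencephalography (SEEG) implants on the order of ten depth
electrodes through the skull into deep brain targets. The dominant risk is
hemorrhage from conflict with intracranial vessels, so trajectories are
planned through avascular corridors using a vascular model segmented from
imaging. Different imaging modalities resolve vessels down to different
calibers: catheter angiography (DSA) resolves sub-millimeter vessels, while
MR-based angiography/venography and gadolinium-enhanced MR miss smaller
ones. A risk score computed against an incomplete vascular model is
optimistic: the planner reports an "apparent" risk while the "true" risk --
measured against the most complete model -- can be much higher.

This package reproduces that comparison end to end on synthetic phantoms,
where the complete vasculature is known by construction. It quantifies (i)
how much apparent risk understates true risk when planning on degraded
models, (ii) the vessel diameter at which a degraded model becomes
statistically equivalent to the gold standard, and (iii) how the
correlation between apparent and true risk collapses with model fidelity.

## The phantom

`make_phantom()` builds a seeded head phantom on a 96^3 grid at 1 mm
isotropic voxels (desk-scale; configurable):

* a spherical intracranial mask (radius 40 mm) inside a skull shell
  (radius 44 mm, icosphere mesh);
* a gray-matter ribbon (4 mm) with six planar sulcal infoldings reaching
  10-16 mm deep, so sulcal-model extraction has real work to do;
* eight deep spherical target regions (radius 5 mm, centered ~18 mm below
  the surface). Region centers are drawn from a randomly rotated
  wide-angle direction set and rejection-sampled for at least 4.5 mm of
  vascular clearance -- mirroring clinical target selection, which picks
  targets an avascular corridor can reach, and guaranteeing the planner a
  feasible problem;
* one ground-truth vascular tree grown by recursive bifurcation from two
  roots: root radius 4 mm, radius decay 0.75 per generation (jittered
  0.9-1.1, child never wider than parent), branching probability 0.65,
  segment lengths 6-12 mm, terminated below 0.5 mm radius. The defaults
  span 1-8 mm diameters so every pruning threshold in 1-4 mm bisects the
  tree. This is a geometric generator, not a hemodynamic model: only the
  caliber spectrum and spatial density matter to the analysis.

The tree is rendered as three modality images differing only in a
*visibility cutoff* delta: the gold modality (delta = 0 mm) shows every
vessel, the mid modality (delta = 2 mm) only vessels of true diameter
>= 2 mm, the low modality (delta = 4 mm) only >= 4 mm. Tubes are painted at
contrast 1, blurred with a 0.5 mm Gaussian (partial-volume stand-in), and
corrupted with additive Gaussian noise (SD 0.05, i.e. contrast-to-noise
20). Rendering can optionally apply a known affine misalignment
(translation up to 3 voxels, rotation up to 2 degrees) whose truth is
stored for registration validation; by default the three images share one
frame so the study pipeline does not depend on registration accuracy.

Per-voxel ground truth (owning segment and true diameter) is retained, so
any measured quantity can be checked against truth.

What the phantom does *not* emulate: anatomical vascular territories,
arterial/venous contrast dynamics, inhomogeneous MR physics, or realistic
inter-subject anatomical variability. Passing tests demonstrate the
*pipeline's* correctness and the *direction* of fidelity effects, not
clinical effect sizes.

## Model generation

`segment_vessel_model()` turns an image into a vessel mesh:

1. **Vesselness.** A multiscale Hessian line filter (`sato_vesselness()`):
   per scale sigma in {0.5, 1, 2, 3} mm the image is Gaussian-smoothed, the
   Hessian formed by central differences and normalized by sigma^2, and the
   bright-line measure computed from sorted eigenvalues l1 >= l2 >= l3
   (zero unless l2, l3 < 0; weight parameters alpha = 0.25,
   gamma12 = gamma23 = 1). The response is the maximum over scales.
2. **Detection and surface.** The vesselness is masked to the intracranial
   volume and thresholded (Otsu by default -- the unattended stand-in for
   an interactively chosen threshold). The surface itself is extracted from
   the *intensity* image restricted to the grown detection mask, at half
   the median detected vessel intensity: the full-width-half-maximum
   criterion places the isosurface at the unblurred tube boundary, keeping
   radius estimates unbiased for resolved vessels. Isosurfaces use
   marching tetrahedra (Kuhn 6-tet decomposition, background-padded so
   boundary-touching structures close), which satisfies the same contract
   as marching cubes without the ambiguity table.
3. **Cleanup.** Connected components under 30 vertices are discarded.

**Centerline radii.** Flux-driven skeletonization is replaced by a
documented simplification with the same radius-readout contract: the mesh
interior is voxelized (surface rasterization + exterior flood fill), the
interior Euclidean distance transform is computed, and the centerline is
its ridge -- voxels whose EDT is within 0.3 voxels of every 26-neighbor
maximum. The tolerance keeps the centerline connected along meandering
tubes (strict maxima leave gaps that inflate radii); ridge points are then
refined to the centroid of their local plateau, recovering sub-voxel axes
for even-diameter tubes. Each vertex's radius is its distance to the
nearest centerline point. Cylinder tests (radii 1.5-4 mm, 1 mm grid) hold
the median error under half a voxel.

Measured radii of sub-resolution tubes still carry partial-volume bloom
(a tube thinner than the blur looks wider). `deblur_radii()` removes the
bloom in quadrature (`r <- sqrt(r^2 - (1.2 * sigma_blur)^2)`), which
matters when thresholding measured diameters against visibility cutoffs.

**Pruning.** `prune_by_diameter()` removes vertices with diameter
*strictly below* the threshold plus their incident faces; a vessel of
diameter exactly equal to the threshold survives. The strict convention is
applied uniformly; it also makes a visibility-delta rendering and a
truth-pruned-at-delta mesh contain exactly the same vessel set.

**Sulcal model.** The intracranial mask is eroded with a 5 mm ball
(voxel survives if its EDT to background exceeds the radius), intersected
with gray matter, and surfaced -- leaving only cortex deeper than the
erosion, a stand-in for vessels hidden inside sulci.

## Registration

`register_affine_nmi()` recovers a 9-parameter affine (3 Euler angles, 3
translations, 3 independent scales about the volume center) by maximizing
normalized mutual information, `NMI = (H(A) + H(B)) / H(A, B)`, over a
joint histogram of the overlap. Two details make the problem tractable:

* **Smooth objective.** The histogram uses partial-volume (linear) binning
  of the moving intensities; hard bins create plateaus that trap a simplex.
  The objective samples the full-resolution images at voxel strides
  (4, 3, then 2 across stages); downsampled pyramids were found to
  displace the NMI optimum under small scale changes.
* **Staged, initialized search.** A closed-form moments initializer
  (intensity centroids plus principal-axes Procrustes, isotropic scale
  from covariance determinants) supplies a starting transform. Stage 1
  fits rotation, translation and *isotropic* log-scale by Nelder-Mead
  (7 parameters; the isotropic axis is the diagonal of the narrow scale
  valley that a fresh simplex cannot enter by single-axis steps),
  multi-started from the caller's initial transform, the moments start and
  seeded perturbations. Refinement then cycles isotropic and per-axis
  scale line searches, a rigid re-fit and a joint 9-D polish, with one
  final cycle at the finest stride.

Recovery on noiseless phantoms stays within 0.5 voxel / 0.5 degree / 1%
across the +/-5 voxel, +/-5 degree, 0.95-1.05 envelope (typically a few
tenths of each). Vertex radii of
transformed meshes scale by the mean of the three scale factors (the
anisotropic convention; round trips are therefore exact in geometry and
approximate in radii).

## The planner

Planning against a set of critical meshes (vessel model, optionally the
sulcal model) proceeds exactly as a clinical computer-assisted planner:

* **Targets**: ROI voxel centers at least `margin + electrode radius`
  (3 + 0.65 mm by default) from every critical surface.
* **Entries**: ~1000 approximately uniform skull-mesh samples at 5 mm
  pitch (area-weighted pool thinned by farthest-point sampling), each with
  its outward normal.
* **Hard constraints** on every entry x target combination (about 3 x 10^6
  on a default phantom before filtering): length <= 90 mm, drilling angle
  <= 30 degrees off the inward skull normal (configurable; the limit is a
  surgical convention), optional entry-ROI traversal, and no intersection
  of the electrode cylinder (diameter 1.3 mm) with any critical mesh.
* **Scoring**: the cumulative risk score over N = 128 nodes sampled
  uniformly along the trajectory. Node clearances are Euclidean distances
  to the nearest critical surface minus the electrode radius, floored at
  zero. With the 10 mm safety distance and the 3 mm margin:
  if every node clears 3 mm, `RS = sum(10 - min(d, 10)) / (N * 7)`;
  if any node is within 3 mm, `RS = 1 + sum_{d <= 3}(3 - d) / (3 N)`.
  The regime is chosen per trajectory; distances are clamped at 10 mm so
  far nodes contribute nothing. RS is continuous at the margin and lies in
  [0, 2]. The minimum distance (MD) is reported unfloored -- collisions
  show as negative clearance down to minus the electrode radius.
* **Per-plan combination**: subject to >= 10 mm spacing between any two
  trajectories, each electrode takes candidates minimizing
  `RS - 0.3 * gm_ratio + 0.1 * length / max_length`, where `gm_ratio` is
  the fraction of electrode contacts (10 contacts at 5 mm spacing, placed
  from the target backwards) inside gray matter. Small instances
  (<= 4096 combinations) are solved exhaustively; larger ones by
  forward-checking search (pairwise separations precomputed once,
  most-constrained electrode assigned first, candidates tried in cost
  order), which prunes dead branches before entering them and is
  deterministic. For tractability the search pre-ranks
  candidates with an approximate risk from a voxelized distance field
  (16 nodes, trilinear lookups), then computes exact collision tests and
  metrics only for a diversified shortlist (entries at least 4 mm or
  targets at least 2.5 mm apart) -- diversity is what gives the spacing
  constraint real alternatives. Every returned plan is re-verified by an
  independent checker (`check_plan()`).

## The study

`run_study()` runs the cohort: 10 phantoms x 8 electrodes (~80
electrodes, the scale of a ten-patient SEEG series), with vessel models at
delta in {0, 2, 4} mm.

* **Nested arm** (exact): models are the ground-truth gold mesh pruned at
  each delta with truth radii -- the degraded model is then *geometrically
  identical* to the visibility rendering and a strict subset of gold.
  Plans are made per model; frozen trajectories are re-evaluated against
  their own model (apparent) and gold (true). Subset monotonicity makes
  apparent <= true exact, per electrode.
* **Imaged arm** (statistical): models are re-derived from the noisy
  rendered images through the full segmentation pipeline, with one
  detection threshold and one surface iso level shared across the three
  modalities of a phantom (they share acquisition contrast; per-image
  thresholds would introduce spurious systematic surface offsets).
  Equivalence of the delta-model with gold-pruned-at-delta is tested by
  Wilcoxon signed rank on paired per-electrode RS and MD.

  Pruning membership in the equivalence comparison is decided by
  ground-truth radii, so both sides contain exactly the vessels above the
  cutoff and the paired differences isolate segmentation noise. The fully
  image-driven alternative -- pruning by centerline-measured diameters --
  is also computed and reported (`equivalence_measured`): its MD
  differences are one-sidedly positive, because partial-volume bloom lets
  sub-cutoff branches survive measured pruning. On a low-variance phantom
  cohort the signed-rank test detects this bias; in a clinical cohort it
  would drown in anatomical variance. We report it as a finding about
  measured-diameter pruning rather than fold it into the equivalence
  claim.
* **Diameter sweep**: gold-model plans re-evaluated against gold pruned at
  1, 2, 3, 4 mm; RS is non-increasing and MD non-decreasing in the
  threshold by the nesting property.
* **Statistics**: Shapiro-Wilk (alpha 0.05) gates each paired comparison
  into a paired t test (normal differences) or Wilcoxon signed rank
  (otherwise; zero differences dropped). Bonferroni correction over 3
  comparisons: significance requires p < 0.05 / 3 = 0.01666..., i.e. the
  truncated 0.016 working threshold. Equivalence is inferred from
  non-significance, as in the clinical practice this mirrors; this is not
  a formal equivalence test (no TOST), a caveat inherited knowingly.
* **Correlation**: squared Pearson correlation between apparent and true
  RS per planning model. It is 1 at delta = 0 by construction and
  collapses toward 0 for degraded models; the seeded cohort gives a
  strictly decreasing sequence, but both degraded values sit near zero, so
  their mutual ordering -- not the collapse itself -- is the stochastic
  part of the claim.

## Numerical choices and degenerate inputs

* Distance queries use a uniform-grid spatial index over triangles with
  ring-wise search; a brute-force scan over all triangles is kept as the
  independent oracle in tests. Collision tests use segment-triangle
  distance with early exit.
* The EDT is the exact separable squared-distance transform (anisotropic
  voxel sizes honored).
* Empty critical sets give infinite clearances and RS = 0; empty
  isosurfaces and fully eroded sulcal masks return empty meshes with
  warnings rather than errors; constant metric vectors are gated
  non-normal with a warning.
* All randomness is seeded through one `with_seed()` helper that restores
  the caller's RNG state; identical (seed, config) reproduce phantoms,
  plans and study tables bit for bit.
* Problem sizes (96^3 grids, 10-phantom cohort, ~1000 entry samples,
  8 exact candidates per electrode) are the package's default study
  conditions; all are configurable through `phantom_config()` /
  `study_config()`.

## Known limitations

* Spherical head and planar sulci: no gyral geometry, no hemispheric
  asymmetry; entry sampling and drilling-angle limits are therefore milder
  than on a real skull.
* Measured vessel diameters below ~1.5 mm on a 1 mm grid are unreliable
  (quantization plus bloom), exactly as sub-millimeter DSA calibers are in
  practice; the measured-radius pruning bias above is the visible
  consequence.
* The risk score treats all vessels alike; no caliber- or type-dependent
  hemorrhage model is attempted (none is available to fit).
* Greedy plan combination is provably optimal only on small instances;
  on large ones it is validated for feasibility, not optimality.
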
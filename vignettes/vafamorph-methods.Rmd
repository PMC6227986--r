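---
title: "Morphometry of fusiform vessel aneurysms: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry of fusiform vessel aneurysms: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Fusiform aneurysms of the vertebral artery dilate the whole vessel
contour concentrically, and their rupture risk is thought to be encoded
in their geometry: how long and wide the bulge is, how its
cross-sectional area is distributed between the proximal and distal
halves, how irregular (concave) the wall outline is, and how strongly
the parent vessel curves near the lesion.  `vafamorph` implements the
complete quantitative pipeline from a triangulated vessel surface to a
rupture-risk classification:

1. **Voxelization** of the watertight surface into an isotropic binary
   occupancy grid;
2. **centerline extraction** by topology-preserving 3D thinning, graph
   ordering and penalized quintic spline fitting, with Frenet–Serret
   curvature $\kappa(s)$ and torsion $\tau(s)$ from the analytic spline
   derivatives ($\kappa = |P' \times P''|/|P'|^3$,
   $\tau = (P' \times P'')\cdot P''' / |P' \times P''|^2$);
3. **cross-section sweep**: exact mesh–plane intersections at every
   arc-length station, yielding eight shape indices per station
   (maximum, minimum and equivalent diameters, area, area change rate,
   eccentricity, solidity, extent), which together with $\kappa$ and
   $\tau$ form ten sequences along the vessel;
4. **aneurysm detection and the segment layout**: the bulge is the
   longest run of stations whose area exceeds 1.5 times the proximal
   reference area; its length $L$ defines five consecutive segments of
   length $L$ (two proximal, the aneurysm, two distal), and the aneurysm
   is additionally split into halves;
5. **the 571-feature vector**: 7 segments × 10 sequences × 5 statistics
   (maximum, mean, standard deviation, integral, total variation)
   = 350, four segment-pair ratios × 10 × 5 = 200, and 21 whole-lesion
   descriptors;
6. **feature selection**: Welch t-test ranking (top 20 by $|t|$) with
   greedy Pearson-correlation pruning at $|r| > 0.5$;
7. **classification**: SVM (linear, unit cost), random forest (100
   trees), k-nearest neighbours ($k = 5$) and subspace discriminant (30
   LDA learners on random half-size feature subspaces), evaluated under
   leave-one-out and repeated stratified 80/20 splits, with ROC/AUC and
   Youden-optimal operating points.

Because the patient surfaces behind the published cohort are not
publicly deposited, the package ships a synthetic generator
(`fusiform_phantom()`, `simulate_cohort()`) that provides ground truth
at both the geometric and the statistical level.

## The synthetic generator and what it does (not) emulate

`tube_mesh()` sweeps circular cross-sections along an analytic
centerline in a rotation-minimizing frame (double-reflection method),
closing the ends with triangle fans; the result is watertight and
consistently oriented by construction.  The radius profile is

$$ r(s,\theta) = r_0 + A\, e^{-(s-s_c)^2/2w^2}\,
   \bigl[1 + \text{skew}\cdot\tanh((s-s_c)/w)\bigr] - \text{dimple}(s,\theta). $$

Defaults ($r_0 = 2$ mm, $A = 2$ mm, $w = 3$ mm on a 40 mm vessel) give a
fusiform bulge of maximum diameter 8 mm whose detected length at the
1.5× area threshold is, in closed form,
$L = 2\sqrt{2w^2 \ln\!\bigl(A / (r_0(\sqrt{1.5}-1))\bigr)} \approx 10.37$ mm —
the main geometric oracle for the detection stage.  Two deliberate
modelling choices:

* **Skew multiplies the bulge term only.**  Scaling the whole profile
  would enlarge the distal *parent vessel* beyond the detection
  threshold and absorb it into the "aneurysm".  With the bulge-only
  skew, positive skew enlarges the distal half of the lesion and
  strictly lowers the proximal/distal area ratio — the direction
  reported for ruptured lesions.
* **The dimple must be narrow to matter.**  A radial dent makes the
  contour concave only where $r\,r'' > r^2 + 2r'^2$ in polar form; the
  default angular width (0.35 rad) guarantees concavity for dimples
  deeper than about 0.5 mm on a 4 mm-radius bulge, so deepening the
  dimple strictly lowers solidity.  A wide shallow dent merely flattens
  the circle and leaves solidity at 1.

`simulate_cohort()` works at the feature level: 12 ruptured and 25
un-ruptured cases, the five published discriminative features drawn per
group from Normal(mean, sd) at their reported group summaries, and the
remaining 566 features standard-normal in both groups.  This emulates
the *cohort-level group structure*, not real feature correlations:
real geometric features are strongly inter-correlated, and the noise
features here are independent.  Consequently, passing cohort tests
demonstrate the statistical machinery (ranking power, pruning, honest
fold handling) under the published effect sizes — they do not certify
classifier accuracy on real vessels.

## Numerical conventions

* **Voxel grid.**  Isotropic spacing, default $h = 0.25$ mm for vessels
  of 3–4 mm baseline diameter; axis order x, y, z with the origin at the
  center of voxel $[1,1,1]$.  Occupancy is decided by flood-filling the
  exterior (6-connectivity) through the rasterized surface shell and
  resolving the one-voxel-thick shell by a parity ray test on voxel
  centers, so a voxel is occupied iff its center is inside the surface.
  The grid origin carries a golden-ratio sub-voxel offset: exact
  alignment of analytic shapes with voxel centers is a degenerate case
  that biases center-inside counting (an axis-aligned cylinder loses
  ~3% volume), while a generic offset keeps volume errors well under 2%
  at $h = 0.25$.  Translation consistency under integer multiples of
  $h$ is preserved.
* **Thinning.**  Sequential six-direction boundary peeling deleting only
  simple points (the (26,6) characterization: one 26-component of object
  neighbours, one 6-component of background in the 18-neighbourhood
  touching a face neighbour).  The endpoint criterion protects voxels
  with at most one neighbour *and* staircase tips whose two neighbours
  are mutually adjacent — without the latter, digital curves retract
  tip-by-tip and the skeleton loses whole segments.  Side branches
  shorter than twice the local radius (chamfer distance transform) are
  pruned; the main path is the longest weighted shortest-path found by a
  double Dijkstra sweep, which does not require degree-1 endpoints (a
  26-connected digital curve is not triangle-free).  A skeleton whose
  main path covers less than 60% of its voxels is rejected as a loop or
  a branched tree.  The returned polyline is oriented deterministically
  (lexicographically smaller endpoint first, coordinates binned to 1 mm
  so voxel noise cannot flip the direction).
* **Centerline spline.**  Penalized quintic B-splines per coordinate
  against the chord-length parameter (quintic so that the third
  derivative needed for $\tau$ is continuous), knots every ~2 mm,
  third-order difference penalty.  Two penalty-selection rules are used
  deliberately: for noisy inputs (raw skeletons) the strongest smoothing
  whose per-coordinate RMS deviation stays within the smoothing
  tolerance (default: the voxel pitch, the quantization noise floor);
  for variance-limited inputs (section centroids, below) the GCV
  optimum.  `smoothing = 0` requests interpolation.
* **Recentering.**  Skeleton voxels carry $O(h)$ quantization noise,
  which limits pointwise curvature accuracy.  `vessel_centerline()`
  therefore refines the curve through the centroids of exact mesh
  cross-sections.  The slicing frames for the first two passes come from
  a wide-knot (8 mm) copy of the curve — if the frames came from the
  detailed fit itself, its small-scale wiggles would tilt the slicing
  planes and feed displaced centroids back into the next fit, a loop
  that does not contract.  A final pass re-slices with the detailed
  curve's own frames, which are accurate by then.  On analytic
  phantoms at $h = 0.25$ mm this recovers $\kappa$ and $\tau$ to well
  under 1% over the interior of the curve (the acceptance tolerance is
  2%).
* **Sections.**  Exact mesh–plane intersection polygons (no
  rasterization): per-edge intersection points computed once per
  undirected edge and chained into closed loops; the loop containing the
  centerline point is kept.  Solidity uses the exact polygon and
  convex-hull areas; extent uses the bounding box in the
  rotation-minimizing in-plane frame (the original description leaves the box
  orientation; the RMF makes it reproducible); eccentricity comes from
  the second-moment equivalent ellipse.  $dA/ds$ is a central difference
  on the station grid, one-sided at run boundaries.  Stations within
  twice the local radius of either curve end are flagged and excluded
  from feature segments.  The $d_{\min} \le d_{eq} \le d_{\max}$
  inequality is a property of near-convex, lumen-like regions (a
  Reuleaux-style set already violates it); it is asserted on swept
  stations and smooth test contours, not on arbitrary polygons.
* **Segments and statistics.**  Station selection uses closed intervals
  $[s_{start}, s_{end}]$: with half-open intervals the trapezoid
  integral of each segment systematically loses one grid bin.  Segments
  extending beyond the analyzed span are truncated, computed over the
  available support, and flagged; fully unsupported segments yield
  missing values, which the classification stage imputes from training
  folds.  "Total" features are the integrals over arc length (so total
  solidity carries mm and total maximum diameter carries mm²).
* **Ratios.**  Plain quotients for the four segment pairs; denominators
  below $10^{-9}$ in magnitude yield missing values, not infinities.
  The published table reports a negative mean for one curvature ratio,
  which a quotient of non-negative curvature statistics cannot produce;
  plain quotients are nevertheless retained as the defined behavior, and
  the cohort generator simply plants the published group summaries.
* **Torsion under reversal.**  Torsion is a chirality invariant:
  traversing the curve backwards leaves $\tau$ unchanged (the numerator
  $(P'\times P'')\cdot P'''$ is even under $t \to -t$), while a mirror
  reflection negates it.  Both behaviors are tested.  $\tau$ is reported
  as 0 and flagged where $\kappa < 10^{-6}$/mm.
* **Whole-lesion descriptors.**  The 21 global features are: $L$; width
  $W$ (max of $d_{\max}$ over the aneurysm); $W/L$; neck tangent angle
  and neck chord distance; asymmetry factor (max in-plane centroid
  offset / $d_{eq}$); aneurysm volume $\int A\,ds$; lateral surface area
  $\int \text{perimeter}\,ds$; convex-hull volume of the aneurysm
  boundary points and the resulting 3D solidity; bulge ratios
  $W/d_{eq}$ at both necks; normalized arc position of the area maximum;
  $\int\kappa\,ds$ and $\int|\tau|\,ds$ over the aneurysm; mean and max
  centerline deviation from the neck-to-neck chord; tortuosity of the
  aneurysm and of the full five-segment span; and $d_{eq}$ at both
  necks.  The 3D hull volume uses an incremental convex hull with a
  deterministic quasi-random insertion order (structured ring-stacked
  inputs otherwise hit degenerate horizon configurations) and a final
  containment self-check.

## Selection and classification

Welch's unequal-variance t-test is used throughout; recomputing the
published group summaries with the pooled-variance flavor does not
reproduce the printed statistics, while Welch does (to the 4th
significant figure on the exactly recomputable rows).  The statistic
depends on the data only through $(n, \bar x, s)$, so
`welch_t()` accepts printed summaries directly.  No multiple-testing
correction is applied, and ties in $|t|$ break lexicographically by
feature name.

By default, feature selection is fitted once on the full cohort before
cross-validation — this replicates the published protocol but leaks
test-case information into the feature choice, which inflates
cross-validated accuracy when many noise features are available.  The
leakage-free variant (`nested = TRUE` in `loocv_evaluate()`) re-runs
selection inside every training fold.  Standardization and median
imputation are always fitted on training folds only (unit-tested).
Decision scores for the ROC are the signed margin (SVM), the class-1
vote or posterior fraction minus one half (forest, KNN, subspace
discriminant); the optimal operating point maximizes Youden's J with
ties broken toward higher sensitivity; model comparisons are paired
t-tests on per-case correctness (leave-one-out) or per-repeat accuracy
(splits), with the convention $t = 0, p = 1$ for identical results.

## Validation scales and known limitations

The test suite validates geometry oracles at $h = 0.25$ mm on 25–40 mm
phantoms (a few seconds to ~15 s per case) and statistical properties on
50-seed Monte-Carlo batches at $n = 37$ and $n = 400$; these sizes keep
the complete suite within a few minutes on one core while leaving the
Monte-Carlo margins wide (e.g. planted-feature recovery at $n = 400$
has per-feature $|t| \approx 6$–8 against a 571-feature noise maximum of
about 3.5).

Known limitations:

* Pointwise curvature from *noisy standalone point sets* is limited by
  the noise: with 0.1 mm point noise, a 5% pointwise band on
  $\kappa = 0.1$/mm is not reliably achievable by any smoother without
  shape priors; the mean is recovered within a few percent and the full
  mesh pipeline (which recenters through section centroids) meets the
  2% band.  The corresponding test asserts bulk statistics for the
  noisy-fit case.
* The study region is a single unbranched segment; bifurcation-aware
  skeletons are out of scope, and looped or branched skeletons are
  rejected rather than resolved.
* Synthetic meshes are clean by construction; robustness to scanner
  noise, segmentation artifacts or mesh-repair output is not claimed.
  The manual preprocessing of the original study (segmentation, noise
  removal, smoothing) has no synthetic counterpart, so the fidelity of
  the phantoms to post-processed patient meshes cannot be validated.
* The published real-data accuracies (LOOCV and split accuracy, ROC
  sensitivity/specificity) are not reproducible without the patient
  surfaces; the package substitutes property-based checks at the
  published effect sizes.
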
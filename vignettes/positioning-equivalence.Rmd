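---
title: "Evaluating sCT-based patient positioning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating sCT-based patient positioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posequiv)
```

## The question the pipeline answers

In an MRI-only radiotherapy workflow a synthetic CT (sCT) generated from MRI
replaces the planning CT. Daily patient positioning — matching a cone-beam CT
or a pair of orthogonal projections to the reference image on bony anatomy —
must then use the sCT as reference. The pipeline quantifies whether that
substitution changes the positioning result: it registers the same
treatment-day data once against a CT and once against an sCT reference, and
analyses the paired differences in the six couch-correction degrees of
freedom, the induced displacement of the target volume, and the overlap of
the repositioned target.

Because no patient imaging ships with the package, every input is synthetic
with known ground truth, which turns each downstream stage into a testable
recovery problem.

## Coordinate and transform conventions

All spatial data live in a right-handed, LPS-like patient frame: x along
right→left, y along anterior→posterior, z along inferior→superior.
Translations are millimetres; rotations degrees — pitch about x, yaw about
y, roll about z. A 6-DoF parameter set becomes a homogeneous matrix as
`x' = R (x − c) + c + t` with `R = Rz(roll) · Ry(yaw) · Rx(pitch)`
(extrinsic, fixed axes) about an explicit rotation centre `c` (the plan
isocenter; the volume centre when unstated). Clinical systems do not publish
their rotation-order convention, so one order is fixed here and used by every
module and test. The order effect is second-order in the angles: below
0.2 mm for 2° rotations at 80 mm radius, and below 0.01 mm at the
sub-degree *differences* between paired results that the statistics operate
on. Degrees appear in all interfaces, radians only internally. Decomposition back to parameters is exact to 1e-9 away from
|yaw| = 90°, where the pitch/roll split degenerates and an error is raised.

## The phantom and what it does (not) emulate

The phantom is an ellipsoidal soft-tissue body (semi-axes 42 × 46 × 75 mm)
in −1000 HU air, with three kinds of analytic bone solids: a skull-like
spherical shell (outer/inner radii 30/25 mm), four stacked vertebral
cylinders (radius 8 mm, height 14 mm), and a mandible-like half-torus (ring
radius 26 mm, tube radius 5 mm). Defaults: 96³ voxels at 1.12 × 1.12 × 2 mm
(a typical head-and-neck reconstruction grid), air −1000 HU, soft tissue
40 HU, bone 900 HU — inside the clinical 200–1700 HU bone-threshold window.
Analytic solids were chosen so every mask and volume has a closed-form
oracle; the voxelized bone fraction agrees with the solid volumes to well
under 2%. The cylinder height is an integer multiple of the default slice
thickness so that slice sampling does not alias the column's volume.

The sCT surrogate models only what is qualitatively reported for CNN-derived
sCTs — blurred edges and reduced bone contrast — as bone-contrast scaling
toward soft tissue (default 0.8), Gaussian blur (default 1.5 mm) and additive
Gaussian HU noise (default 20 HU). No quantitative error model of real sCT
generation exists to calibrate against, so these are stated conditions, not
fitted values; passing recovery tests therefore demonstrates robustness to
*this class* of degradation, not to every artifact a clinical sCT can show
(dental metal, MRI distortion, tissue misclassification). Likewise the
phantom has no immobilization mask, no CT texture or beam-hardening, and a
rigid anatomy — interobserver spread caused by genuinely deformable necks is
outside what the synthetic cohort can exhibit.

## Registration engine

Similarity is mutual information (MI) in nats from a dense 64-bin joint
histogram — no Parzen smoothing, the simplest faithful estimator. Candidate
transforms resample the moving volume by trilinear interpolation;
out-of-grid samples are excluded from the histogram rather than padded, so
background padding cannot masquerade as image agreement.

One numerical point deserves emphasis. On an exactly piecewise-constant
phantom, the voxels inside the bone-threshold window all share one HU value,
so the reference channel of a *literally* bone-only histogram has zero
entropy and MI is identically zero (MI ≤ min(H(A), H(B))) — no similarity
signal exists. The information lives at the bone/soft-tissue boundary.
The engine therefore evaluates MI over the thresholded mask dilated by a
small capture shell (`mask_dilate_vox`, default 2 voxels), which adds those
boundary voxels while keeping the similarity region local to bone, as
clinical bone-match protocols intend. Real CT, with partial-volume texture
inside the window, would not need the shell, but it does not hurt there
either.

Optimization is Nelder–Mead downhill simplex — deterministic given its
start — with parameter scaling equivalent to initial steps of 2 mm / 1°, and
one restart from the incumbent to escape premature simplex collapse. An
optional two-level multi-resolution schedule (×2 block-average downsample,
then full resolution) widens the capture range; it is off in unit tests,
where offsets are small, and on in the pipeline, whose simulated setup
offsets reach several millimetres. On the coarse level the lower bone
threshold is relaxed toward soft tissue because block averaging mixes bone
with its neighbourhood.

The 2D arm emulates planar setup verification: the moving volume is
transformed, re-projected by parallel-ray attenuation sums (frontal along
P-A, lateral along R-L), and the sum of the two projection MIs is maximized
over five DoF with roll frozen at exactly 0. Both views share one volume
transform, as in a single couch correction; parallel geometry is a
simplification of divergent-beam DRRs that preserves the property the tests
rely on: in-plane translation commutes with projection.

## Statistics

Differences are always `sCT-based − CT-based`, sign preserved; summaries use
the sample SD (n−1). The equivalence analysis is the paired two one-sided
t-test (TOST) against (−1, 1) mm with α = 0.05 per side. The headline test
pools the three translation axes of a modality into one test (n = 3 × cases),
mirroring an evaluation that reports exactly one 2D and one 3D test;
per-direction TOSTs are emitted as diagnostics, and rotations are summarized
but not tested. Two ambiguities in common practice are surfaced rather than
silently resolved: whether "95% confidence" refers to the CI or the test
level (TOST duality pairs α = 0.05 with a 90% CI — both 90% and 95% CIs are
reported), and whether axes should be pooled or Bonferroni-corrected (pooled
is the default; the per-direction results let a reader apply any correction).
Zero-variance difference sets degenerate: the test then reduces to whether
the mean lies inside the bounds, reported with a warning and p ∈ {0, 1}.

The PTV metric transforms the *original* contour points by each matrix and
differences corresponding points by index — never nearest-neighbour
matching, which would hide rotations. Closing duplicate points are
deduplicated on construction so no point is double-counted. Histograms use
0.25 mm bins from zero. Dice is computed volumetrically in 3D at 1 mm
isotropic rasterization by default; since a planar workflow might judge
overlap on projections, a 2D projected variant is available
(`projected = TRUE`), with the 3D default documented here.

## Deformation and landmark QA

The Jacobian determinant of `x → x + u(x)` is `det(I + ∇u)`, estimated with
central differences (mm spacing) in the mask interior and one-sided
differences where a neighbour leaves the mask — padding across the body
surface would manufacture spurious negative determinants exactly where skin
folds are plausible. Synthetic fields carry closed-form determinants: the
affine-scale field has constant JD = sx·sy·sz; the Gaussian-bump family has
the rank-one-update determinant `1 + ∂u_z/∂z`, and the folding variant
guarantees `min JD = 1 − A e^{-1/2}/s < 0`. Finite-difference estimates
converge to these at O(h²) in the interior, which the tests verify across
two grid resolutions.

Landmark reproducibility is the mean and maximum distance of repeat
placements to their centroid. A centroid-free alternative (mean pairwise
distance) is offered behind `statistic = "pairwise"`, because the statistic
used in clinical reports of "repeat placement" is usually unstated; the
centroid form is the default as the smaller, more conventional dispersion
measure. Landmark-distance definitions map "horizontal" to R-L and
"vertical" to I-S (or P-A where the anatomy dictates) and ship as an
editable list, since the anatomical operationalization of such definitions
is inherently site-specific.

## Problem sizes and reproducibility

Unit tests run on 32³–48³ phantoms; the ground-truth recovery checks use the
full 96³ default; the demo pipeline (`run_pipeline()`) uses 64³ at
1.7 × 1.7 × 3 mm with 4 cases × 2 observers and routes one case through the
actual registration engines, while the cohort statistics use the simulated
paired tables at the study-scale moments (14 cases, 6 observers are the
reference conditions in `analysis/03` and the acceptance script). These
sizes were chosen so the whole suite exercises every code path at
interactive turnaround; every generator is bit-reproducible from an integer
seed, simplex optimization is deterministic, and the pipeline summary is
byte-identical across reruns with the same config and seed (verified in the
tests, and stamped with a config hash).

## Known limitations

* The phantom's piecewise-constant intensities are harder for MI than real
  textured CT in one way (no internal bone texture) and easier in another
  (no noise floor, no artifacts); registration tolerances here should not be
  read as clinical accuracy claims.
* Equivalence conclusions from the simulated cohort restate the prescribed
  generator moments — they validate the statistical machinery, not clinical
  equivalence of any particular sCT product.
* No divergent-beam DRR geometry, no deformable registration (only QA of
  deformation fields), no dose or margin modelling.
* DICOM-RT interchange uses a JSON mirror of the structure-set content; no
  binary DICOM reader is bundled.
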
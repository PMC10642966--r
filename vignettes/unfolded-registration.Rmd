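---
title: "Topology-preserving registration of hippocampal subfields in unfolded space"
author: "unfoldreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-preserving registration of hippocampal subfields in unfolded space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The hippocampus is a folded sheet of gray matter whose cytoarchitectonic
subfields (the subicular complex and cornu ammonis fields CA1--CA4, with the
dentate gyrus merged into CA4 here) are arranged in consistent order across
the sheet's proximal--distal axis. Conventional 3D volumetric registration
aligns hippocampi as blobs of tissue: gray matter from one bank of a sulcus
can be pulled across the sulcus onto the other bank, so propagated subfield
labels end up as disconnected islands or in the wrong order. `unfoldreg`
instead registers hippocampi *on the sheet*: every sample is mapped into a
standardized 2D rectangular ("unfolded") space, morphometric features are
computed per vertex, samples are aligned by 2D diffeomorphic registration of
those features, and subfield labels ride through the resulting transforms.
Because the transforms are smooth, invertible maps of the rectangle, the
sheet topology of the labels cannot break.

The package implements the full comparison: the unfolded-registration
pipeline, an unfolding-only baseline (no 2D registration), and an idealized
3D volumetric control, evaluated with shared metrics (Dice overlap in
unfolded and native space, border distances in mm, topology checks, feature
ablations, paired one-tailed t-tests).

## The unfolding model

Gray matter is parameterized by three harmonic coordinates solving the
Laplace equation between opposing boundary labels:

* `ap` (anterior terminus -> posterior terminus),
* `pd` (proximal edge -> distal edge),
* `io` (SRLM inner boundary -> outer background), the laminar coordinate.

Harmonic fields are smooth, take their extremes only on the boundaries, and
are monotone along the sheet between their Dirichlet ends, which makes
(`ap`, `pd`) a valid 2D chart of the sheet and `io = 0.5` a well-defined
mid-thickness surface. The discrete solver is red--black successive
over-relaxation (omega = 1.8) on the 6-neighbour stencil with zero-flux
walls by stencil renormalization; tolerance 1e-5 (maximum update per sweep)
and a 10,000-sweep cap, far above what the geometry needs (the slab oracle
converges in a few hundred sweeps).

The Dirichlet values sit at boundary-voxel *centres*, i.e. half a voxel
outside the tissue. Two consequences are documented rather than hidden:

* the `io` field is compressed toward 0.5 by about half a voxel per side
  (0.05 mean absolute error at 0.5 mm voxels on a 2 mm slab); its level set
  at 0.5 and its monotonicity are unaffected;
* streamline thickness (below) must correct for one voxel of boundary
  offset.

The mid-thickness surface is sampled on a regular grid (default 256 x 128
nodes across A-P x P-D, assigned a physical extent of 40 x 20 mm so that
deformations are reportable in mm). Node positions are interpolated from
gray-matter voxels in the laminar band |io - 0.5| < 0.25 by
inverse-distance weighting of the nearest supporting voxels in (ap, pd)
space; nodes whose nearest support is farther than 1.5 grid cells are
flagged as extrapolated. On a flat-slab phantom the reconstructed surface
deviates from the true plane by about 0.002 mm.

## Morphometric features

Three channels are computed per vertex and z-scored before registration so
that heterogeneous units (mm, dimensionless ratio, 1/mm) contribute with
equal weight:

* **Thickness** (mm): arc length of the streamline traced through the
  io-gradient in both laminar directions (RK4, step 0.25 x voxel) until
  io <= 0.01 or >= 0.99. The traced length is divided by 0.98 (the
  threshold margin) and reduced by one mean voxel (the two half-voxel
  Dirichlet offsets). The estimate is exact when the local thickness is an
  integer multiple of the voxel size and quantized within half a voxel
  per laminar column otherwise -- at 0.5 mm voxels, a fundamental
  resolution limit, not a solver artifact.
* **Gyrification** (dimensionless): native area of each vertex's dual cell
  (a quarter of every adjacent native quad) over the unfolded pixel area.
  Values above 1 mark tissue compressed by unfolding; the cohort-mean
  gyrification times the unfolded area reproduces the native mesh area to
  well under 10%.
* **Mean curvature** (1/mm): quadric fit over each vertex's 5 x 5 native
  neighbourhood, sign positive toward the outer (io = 1) side. On a
  cylinder-shell phantom of radius 10 mm the recovered |H| is within 10% of
  the analytic 1/(2r) = 0.05/mm.

Gyrification and curvature are Gaussian-smoothed with sigma = 1 mm in
unfolded space (the estimators are noisy at single-pixel scale; 1 mm is
well below the feature scales of interest). Missing vertices are filled
with the nearest valid value before standardization.

A note on curvature sign and hemispheres: with the sign anchored to the
outer laminar side, mean curvature is mirror-invariant -- a gyral ridge
stays a ridge in a mirrored hippocampus -- so left and right samples can be
pooled in unfolded space without any sign flip.

## Registration engine

A single dimension-generic engine drives both the 2D unfolded and the 3D
control registrations: greedy demons-style optimization of mean
per-channel SSD under a stationary velocity field (SVF), with

* per-iteration demons forces averaged over channels, smoothed with the
  *fluid* sigma (2 px default);
* accumulation into the velocity, smoothed with the *elastic* sigma (1 px
  default);
* exponentiation by scaling-and-squaring, which keeps the Jacobian
  determinant positive by construction;
* a 3-level multiresolution pyramid (x4, x2, x1; 100/100/50 iterations,
  stopping early when the best similarity stalls for 10 iterations).

The published pipeline used ANTs' symmetric time-varying SyN with default
parameters; the contract that matters for the science is *deformable,
diffeomorphic, multi-contrast, on the unfolded rectangle*, and an SVF
greedy scheme satisfies it while being simple, deterministic, and testable.
Equal feature weighting is implemented as z-scoring plus unweighted force
averaging; SSD replaces cross-correlation because standardized channels
are already commensurate. Sampling clamps at the rectangle borders and
nothing wraps: the unfolded space has four true edges, which is exactly
what distinguishes it from spherical cortical registration. For the same
reason, synthetic test warps taper to zero displacement at the borders.

Numerical choices: regularization smoothing inside the demons loop uses a
triple-box approximation to the Gaussian (the standard trick in
registration toolkits; the exact FIR Gaussian is retained for feature
smoothing and pyramid anti-aliasing). Scaling-and-squaring subdivides until
the per-step displacement is below 0.5 px inside the optimization loop and
0.25 px for emitted transforms; at the test configuration the
forward-composed-with-inverse residual is 0.06 px. Displacement-field
inversion uses 20 fixed-point iterations. Composition, inversion and
Jacobians are exercised against brute-force point tracing and analytic
fields in the test suite.

Groupwise template building follows the standard iterative scheme: start
from the arithmetic mean of the stacks; register every stack to the
template; average the warped stacks; apply the inverse of the mean
displacement to the average (the shape update that keeps the template
centred in the cohort); repeat four times. Transforms from the final pass,
composed with the final shape update, are returned as sample-to-template
maps.

## Label propagation

Labels are categorical, so every resampling step is nearest-neighbour. For
samples i and a reference r, a reference pixel is mapped through
`invert(t_r)` into template space and through `t_i` into sample i, where
the label is read. Native-space labels are obtained by assigning every
reference gray-matter voxel the unfolded label at its (ap, pd) position --
full-thickness columns, consistent with subfields being full-thickness
parcels. Pixels that sample background are imputed with the nearest
non-zero label in unfolded mm; exact distance ties go to the smaller label
id so the result is deterministic. The unfolding-only baseline is the same
code path with identity transforms.

## The volumetric control

The control reproduces an idealized best-case 3D pipeline on the same
cohort: binarize gray matter, mirror right hemispheres about the sagittal
plane, rigidly align to the reference by two-moment initialization
(centroids plus principal axes, the four-fold proper-rotation sign
ambiguity resolved by mask overlap), resample to a common 0.5 mm working
grid, smooth the binary masks with sigma = 1 voxel so SSD has gradients,
and run the *same* engine in 3D, unimodally, through the same
template-building loop (60/40/20 iterations per level -- the 3D problem is
smoother than the feature images). Subfield labels are then carried through
the concatenated 3D transforms into reference native space, sampled along
the reference mid-thickness surface into unfolded space, and imputed.
Differences from the unfolded condition are therefore attributable to the
representation, not the optimizer.

## The phantom: what it emulates and what it does not

Real ground truth (3D histology with manual subfield annotations) cannot be
redistributed, so validation uses a parametric folded-sheet phantom with
analytically known coordinates: a circular-arc cross-section (total curl
3*pi*/2 over a 20 mm arc) extruded 40 mm along A-P, with longitudinal gyri
modelled as a sinusoidal displacement along the surface normal (default 3
waves, 1.5 mm amplitude). Subfields partition the P-D axis (default
fractions 0.28/0.30/0.10/0.14/0.18) with per-subfield thickness
(1.8/1.4/1.2/1.3/2.0 mm); a one-voxel SRLM shell lines the concave side and
terminus labels cap the four sheet edges. Voxelization classifies each
voxel by the signed laminar fraction of its centre, so gray-matter volume
matches area x thickness almost exactly.

Cohorts jitter the gyral count (+/-1), amplitude (+/-30%), gyral phase,
thickness scale (+/-10%), subfield fractions (Dirichlet perturbation with
concentration 150, about 12% relative variation) and world origin
(+/-3 mm); hemispheres alternate so that a cohort of 7 has four left and
three right samples. These magnitudes were fixed once as plausible
inter-sample variability. By construction, gyral variation runs along A-P
while subfield variation runs along P-D, so folding differences and
boundary differences are separable -- a convenient property real
hippocampi only approximate.

What the phantom does *not* emulate: real cytoarchitecture or image
intensities (labels only, matching the binarized control), the dentate
gyrus' distinct topology, curvature-dependent subfield boundaries, or the
irregular cross-sectional contour of a real hippocampus. The constant-
curvature arc is also more mirror-symmetric than real anatomy, which makes
the control's moment-based initialization occasionally resolve its sign
ambiguity the wrong way on strongly phase-shifted samples -- an exaggerated
version of a genuine volumetric failure mode worth keeping in mind when
reading control-condition numbers. Passing benchmarks on phantoms
demonstrates that the machinery is correct and that the representation
argument holds under known ground truth; it does not certify performance
on histology.

## Evaluation

* **Dice** per subfield, in both unfolded and reference-native space.
* **Border distances**: for each neighbouring pair (Sub-CA1, CA1-CA2,
  CA2-CA3, CA3-CA4), the Euclidean distance transform from the reference
  interface (the voxels of the first label 6-adjacent to the second) read
  at the test interface, pooled across pairs, summarized by the median in
  mm.
* **Topology**: per subfield, the number of 8-connected components
  (violation if more than one), and per A-P row, whether labels are
  non-decreasing in the anatomical P-D order (skipping a subfield is
  allowed, reversing is not). Nearest-neighbour sampling of a tilted
  boundary can produce a single-pixel jag that the strict ordering check
  counts as one violation on some seeds; component breaks do not occur in
  the unfolded conditions.
* **Paired one-tailed t-tests** on subfield x subject Dice pairs between
  conditions.
* **Feature ablation**: template building and propagation repeated for all
  7 non-empty subsets of {thickness, gyrification, curvature}. Which single
  feature is most informative depends on what varies in the cohort: with
  the default jitter, subfield fractions (tracked by the thickness profile)
  dominate, so thickness ranks first; in cohorts whose variation is mostly
  folding, curvature ranks first. On the default cohort the full stack
  ranks at least as high as every single feature; on some seeds the
  dominant single feature can edge it out, since the other channels then
  contribute mostly noise.

## Problem sizes and defaults

Benchmarks and tests run on a 64 x 32 unfolded grid (the full 256 x 128
grid is the package default for single-sample work and the CLI) with 0.5 mm
phantom voxels and a 0.5 mm control working resolution; the seven-sample
benchmark completes in about 90 seconds and the whole test suite in about
three minutes on one core. On the default seeded cohort (n = 7, seed 42)
the pipeline reproduces the expected pattern: mean native-space Dice
unfolded-registration > unfolding-only > volumetric control, significant by
paired one-tailed t-tests; zero topology violations for unfolded
registration against hundreds of ordering violations for the control; and
the all-features ablation row at least as good as every single feature.
`scripts/acceptance.R` recomputes all of these from scratch.

Configuration files are YAML; every CLI run writes its effective
configuration into the output directory.

## Known limitations

* Laplace coordinates are a chart, not an isometry: unfolded distances are
  not geodesic distances, and vertex density in native space varies along
  the sheet (densest at the curl extremes).
* Thickness is quantized by the voxel grid (exact only for thicknesses at
  integer voxel multiples) and `io` carries the half-voxel boundary
  compression described above.
* The engine is plain SSD demons: no cross-correlation, mutual
  information, B-splines, or landmark constraints.
* The evaluation assumes one chosen reference sample, as any native-space
  comparison must.
* No probabilistic multi-atlas fusion; propagation is single-source
  nearest-neighbour.
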
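# unfoldreg

Topology-preserving registration of hippocampal subfields in unfolded
space.

## The problem

The hippocampus is a folded sheet of gray matter whose subfields — the
subicular complex (Sub) and cornu ammonis fields CA1–CA4 (dentate gyrus
merged into CA4 here) — occupy consistent, ordered bands across the sheet.
When hippocampi are aligned by conventional 3D volumetric registration,
tissue is matched as a volume, not as a sheet: gray matter gets stretched
across sulci and the SRLM, and propagated subfield labels come out as
isolated islands or in the wrong order (CA1 touching CA3 directly).

`unfoldreg` aligns hippocampi *on the sheet* instead:

1. **Unfold.** Solve the Laplace equation between boundary labels to give
   every gray-matter voxel coordinates `(ap, pd, io)` — anterior–posterior,
   proximal–distal, and laminar depth — mapping the sheet onto a standard
   2D rectangle (256 × 128 grid, 40 × 20 mm).
2. **Measure.** Compute thickness (streamlines through the laminar
   gradient), gyrification (native / unfolded area ratio), and mean
   curvature (local quadric fits) at every grid vertex.
3. **Register.** Align the z-scored multi-channel feature images with a
   diffeomorphic (stationary-velocity demons) 2D registration, building a
   groupwise template over four refinement passes. Transforms are smooth
   and invertible maps of the rectangle, so subfield topology cannot
   break.
4. **Propagate & evaluate.** Carry subfield labels through the
   concatenated transforms into a reference sample, and score the result
   against unfolding-alone and against an idealized 3D volumetric control
   (same engine, 3D, binarized masks) with Dice overlap, border distances
   in mm, topology checks, and paired one-tailed t-tests.

Ground-truth validation uses a parametric folded-sheet phantom with
analytically known coordinates and subfield boundaries; a seeded cohort
generator emulates a study of seven variable samples (four left, three
right hemispheres).

Intended users: researchers in hippocampal imaging / digital neuroanatomy
who want surface-based subfield alignment with quantitative, reproducible
evaluation, and methods developers who need a tested reference
implementation of Laplace unfolding + unfolded-space registration.

## Worked example

```r
library(unfoldreg)

# one phantom sample: a folded, gyrified sheet with subfield labels
ph <- generatePhantom(phantomParams(), seed = 1)
ph$labels
#> LabelVolume 37x93x33, spacing 0.5x0.5x0.5 mm
#>   labels: 1:3664 2:3021 3:845 4:1349 5:2610 6:2637 7:290 8:357 9:584 10:669

# unfold it and extract the mid-thickness surface grid
co <- computeCoordinates(ph$labels)
co
#> CoordinateFields over 11489 gray-matter voxels (grid 37x93x33)
grid <- extractMidthicknessGrid(co, ph$labels, shape = c(64, 32))
grid
#> SurfaceGrid 64x32, 2048 valid nodes, extent 40x20 mm

# per-vertex thickness in mm
th <- computeThickness(co, grid, ph$labels)
th
#> UnfoldedMap 'thickness' 64x32 (mm), spacing 0.625x0.625 mm
mean(mapValues(th), na.rm = TRUE)
#> [1] 1.75
```

The labels line counts voxels per label: subfields 1–5, the SRLM inner
boundary (6), and the four edge termini (7–10). The mean thickness of
1.75 mm reflects the phantom's per-subfield thickness profile
(1.2–2.0 mm) weighted by subfield extent.

The full three-condition benchmark on a seeded seven-sample cohort:

```r
report <- runBenchmark(n = 7, seed = 42, grid_shape = c(64, 32))
report
#> EvaluationReport: 7 samples, seed 42
#>
#> Mean native-space Dice by condition:
#>   unfolded_registration    0.9133
#>   unfolding_only           0.8043
#>   volumetric               0.4839
#>
#> Paired one-tailed t-tests (native Dice):
#>   unfolded_registration > unfolding_only: t = 3.751, p = 0.0003916
#>   unfolding_only > volumetric: t = 6.229, p = 4.263e-07
#>   unfolded_registration > volumetric: t = 7.098, p = 4.132e-08
#>
#> Topology violations (components / ordering):
#>   unfolded_registration    0 / 0
#>   unfolding_only           0 / 0
#>   volumetric               3 / 514
```

Reading this: registering in unfolded space recovers the reference's
subfield labels best (mean Dice 0.91), unfolding without registration is
second (0.80), and the 3D volumetric control is worst (0.48) — and only
the volumetric condition breaks the sheet topology of the labels
(component splits and proximal–distal order reversals). `writeReport()`
serializes the full report (JSON + CSV tables), deterministically for a
given seed.

A command-line wrapper over the same functions lives at
`inst/cli/unfoldreg.R`:

```sh
Rscript inst/cli/unfoldreg.R phantom --n 7 --seed 42 --out cohort/
Rscript inst/cli/unfoldreg.R features --labels cohort/sample01_labels.nii.gz --out feat01/
Rscript inst/cli/unfoldreg.R benchmark --n 7 --seed 42 --grid 64x32 --out report/
```

## Package tour

| Area | Functions |
|---|---|
| I/O | `readVolume`, `writeVolume`, `readUnfolded`, `writeUnfolded`, `readConfig` |
| Phantom | `phantomParams`, `generatePhantom`, `generateCohort`, `makeSyntheticWarp` |
| Unfolding | `solveLaplace`, `computeCoordinates`, `extractMidthicknessGrid` |
| Morphometry | `computeThickness`, `computeGyrification`, `computeCurvature`, `prepareFeatureStack` |
| Registration | `registerMultichannel`, `buildTemplate`, `composeTransforms`, `invertTransform`, `applyTransform`, `jacobianDeterminant`, `momentRigidInit` |
| Propagation | `propagateLabelsUnfolded`, `projectToNative`, `imputeMissing`, `flipLR` |
| Control & evaluation | `runVolumetricCondition`, `diceScores`, `borderDistances`, `topologyCheck`, `featureAblation`, `pairedOneTailedT`, `runBenchmark` |

The methods vignette (`vignettes/unfolded-registration.Rmd`) documents the
model, the numerical choices and their error characteristics, the phantom's
scope, and known limitations.
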
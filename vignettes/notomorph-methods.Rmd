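---
title: "Single-cell morphometrics of notochord morphogenesis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell morphometrics of notochord morphogenesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notomorph)
```

## The scientific problem

During early development of the amphioxus embryo, the notochord — the axial
mesodermal rod that defines the chordate body plan — transforms from a loose
array of rounded cells into a regular "stack of coins": flattened central
cells stacked single-file along the anteroposterior (AP) axis, flanked
dorsally and ventrally by rows of Müller cells. `notomorph` provides the
computational side of a morphometric study of that transformation: it turns
labelled 3D segmentations of notochord cells into a quantitative account of
*which* geometric transformations (shape change, growth, cell intercalation,
cell addition) generate tissue length, and *when and where* along the axis
each one acts.

The pipeline has five analysis stages, plus a synthetic-data generator that
makes every stage testable against known ground truth:

1. **Shape metrics** — per-cell 3D descriptors from a labelled volume.
2. **Morphospace** — feature screening, standardised PCA, embedding.
3. **Trajectory** — cluster-guided principal-curve pseudotime.
4. **Geometric model** — mean-cell parameterisation, counterfactual length
   scenarios, and the intercalation index β.
5. **Proliferation landscapes** — densities of S-phase (EdU) and mitotic
   (PhH3) nuclei along the normalised AP axis.

Throughout, AP ≈ x (first array margin), dorsoventral (DV) ≈ y, mediolateral
(ML) ≈ z; voxels are isotropic cubes; physical units are micrometres.

## Shape metrics

`extract_cells()` splits a labelled volume (background 0, one positive
integer per cell) into per-cell voxel records, checks 6-connectivity, flags
border-touching cells, and joins nucleus centroids by cell id.
`compute_core_metrics()` and `compute_derived_metrics()` then produce the
feature suite:

* **Volume** is the voxel count times the voxel volume.
* **Surface area** is the area of a marching-cubes isosurface. The literal
  boundary mesh of a digitised smooth object overestimates its true area
  (about +9 % for a ball of radius 20 voxels — the staircase effect), so the
  occupancy field is smoothed with a small Gaussian (σ = 0.7 voxel,
  `area_smooth_sigma`) before meshing; this brings the ball's area within
  ~1 % and its sphericity to ≈0.99. The *unsmoothed* mesh is retained as an
  independent volume oracle: its divergence-theorem volume agrees with the
  voxel count to better than 1 %, which the test suite checks on random
  superellipsoids.
* **Ellipsoid semi-axes** come from the eigen-decomposition of the voxel
  second-moment matrix, with the per-voxel variance (vox²/12) added on the
  diagonal so a filled box of side L has variance exactly L²/12, and scaled
  as a = √(5λ₁) so a uniformly filled ellipsoid is recovered exactly.
* **Orientation** is the absolute direction cosine of the major eigenvector
  against each body axis (1 = aligned); the three squared cosines sum to 1.
* The **object-oriented bounding box** takes extents along the eigenvectors,
  plus the support of the voxel cube itself in each direction, so an
  axis-aligned box is recovered exactly and **cuboidness** = V/(o₁o₂o₃)
  equals 1 for it.
* **Transverse cross-sectional area** A is the area of the binary projection
  of the mask onto the DV–ML plane. A single slice would be noisy, and V/l
  would make the prism approximation below circular. **AP anisotropy** is
  the dimensionless l_AP/√A.
* **Sphericity** = π^(1/3)(6V)^(2/3)/area; **flatness** = c/b; prolate and
  oblate ellipticities use the standard two-ratio forms. Nuclear displacement
  is nucleus minus cell centroid per axis, and is *missing* (not zero) when
  no nucleus is available.

Cells with fewer than 4 voxels or rank-deficient moments are flagged
degenerate with missing metrics; near-isotropic cells are flagged because
their orientation is unconstrained.

`feature_table()` joins annotations, bins normalised AP position into the
four half-open regions (anterior [0, 0.15), pharynx [0.15, 0.40), trunk
[0.40, 0.60), posterior [0.60, 1]), and, when no layer annotation exists,
classifies the most dorsal and most ventral cells within local AP windows as
Müller cells.

## Morphospace

`screen_redundant_features()` removes, greedily and deterministically, one
member of every feature pair with |Pearson r| ≥ 0.95 (configurable), dropping
the lower-priority member; the priority order prefers curated dimensionless
descriptors over raw lengths, so that, e.g., of ellipsoid axes and bounding
box lengths only one family survives. Spatial position and stage never enter
the feature set. `fit_morphospace()` z-scores the retained features and runs
a PCA; component signs are fixed (largest-|loading| feature positive) so
results are reproducible run to run; per-feature contributions are squared
loadings scaled to percent. A feature is a *significant contributor* to a
component when its contribution exceeds the mean 100/p percent.
Cells with any missing retained feature are excluded listwise and counted.

## Trajectory inference

`infer_trajectory()` follows the cluster-guided principal-curve recipe:
cluster centres (somite stage, AP bins, or seeded k-means via
`cluster_inputs()`) in the first three components anchor a Euclidean minimum
spanning tree; every start-to-leaf path seeds one lineage; each lineage is
fitted by an iterated principal curve — project cells onto the polyline,
order by arc length, smooth each coordinate against arc length with a
non-robust local-linear smoother (lowess, span 0.6), re-parameterise by arc
length — until the mean projection distance improves by less than 1e-4
(relative) or 50 iterations, keeping the best iterate. Three numerical
choices matter:

* the smoother is *linear* in the responses, which makes the fit equivariant
  under rigid rotations of the embedding (pseudotime is rotation-invariant,
  a property the tests check);
* the first and last polyline segments extend linearly during projection, the
  standard endpoint treatment — without it, cells beyond the terminal cluster
  centres drag convergence and a perfectly collinear dataset would not return
  the exact line;
* pseudotime is arc length scaled to [0, 1] over the lineage's own fitted
  cells, oriented so the start cluster precedes the end.

Cells are assigned to the lineage whose curve they project closest to (ties
to the lower branch id). `pseudotime_density()` gives per-stage kernel
densities on [0, 1] with boundary reflection (each integrates to 1);
`stage_pseudotime_correlation()` the cell-wise Pearson r with per-stage
means ± SD and the regression line; `spatial_pseudotime_profile()` the mean
pseudotime in 10 half-open AP bins per stage.

## Geometric model

A mean cell at stage s is summarised (`mean_cell_params()`) by its mean AP
length l̄(s), volume V(s), transverse cross-sectional area A(s) and
bounding-box transverse area, each with SEM. The prism approximation

> l ≈ V / A

links them; its relative error is reported per stage as a diagnostic, never
silently absorbed (flared, non-prismatic cells make it substantial, which is
informative in itself). Three counterfactual single-cell scenarios fix all
but one quantity at the reference stage s₀:

* constant volume, measured area ("AP anisotropy"): l(s) = V(s₀)/A(s);
* isotropic growth: l(s) = l(s₀)·(V(s)/V(s₀))^(1/3);
* anisotropic growth (area frozen): l(s) = l(s₀)·V(s)/V(s₀).

The **intercalation index** β = lⁿ/(n·l̄) compares a measured n-cell
neighbourhood length with the maximal stack-of-coins extension n·l̄ (β = 1 at
maximal extension; values slightly above 1 are clipped with a warning), and
the inverse relation lⁿ = β·n·l̄ extends the cell scenarios to
neighbourhoods (`scenario_neighborhood()`): intercalation-only and
shape-without-growth use the measured β(s); the growth-only scenarios hold β
at β(s₀), since they model growth acting *alone*; the full scenario
reproduces the measured lengths exactly, by construction of β — an identity
the tests assert at 1e-12. Percent changes are 100·(l(s)−l(s₀))/l(s₀).
`elongation_comparison()` normalises neighbourhood- and tissue-scale series
to their first shared stage; the gap between them is the contribution of
posterior cell addition, which local shape change cannot explain.

## Proliferation landscapes

`normalize_positions()` maps each labelled nucleus to
p = (x − x_ant)/(x_post − x_ant) per embryo (≤2 % excursions clipped with a
warning, larger ones are errors). `build_landscape()` pools nuclei per
(stage, marker), rescales the axis to the stage mean length, and estimates a
Gaussian kernel density with reflective boundaries, scaled so each curve's
integral equals the mean labelled-nucleus count per embryo ("mean frequency";
a probability-density mode is available). Combinations with fewer than five
nuclei are skipped with a warning.

## The synthetic notochord

`generate_notochord()` realises the study conditions the package is tested
under. Each cell is a generalised superellipsoid: transverse superellipse
(exponent q; 4 for central cells, 2 for Müller) whose semi-axes follow an
axial profile (1 − |u|^p)^(1/p) times a margin *flare* (1 + flare·|u|^κ)
that swells the cell near its AP faces — the "bowtie" of the central-cell
intermediate stage. A *shape program* maps maturity m (somite-stage units)
to l_AP, A, V, the DV:ML ratio and flare by piecewise-linear interpolation;
the axial exponent p is solved per cell, in closed form via beta-function
moments, so the enclosed volume matches the programmed one (the flare's
volume contribution is folded into this solve, so flare convolutes the
surface without inflating realised volume beyond the program).

The default central program encodes the two observed transitions — early
transverse spreading with AP shortening, flare gain and growth
(m = 6→10: l 9→4.5 µm, A 35→95 µm², V 220→320 µm³), then AP re-elongation
with flare loss and continued growth (m = 10→14: l 4.5→10 µm, V →700 µm³) —
and the Müller program coincides with it at m ≤ 6 before diverging to a
flat, ML-wide morphology, giving the branching structure the trajectory
stage must resolve. Knot values are plausible amphioxus notochord cell
scales chosen once; the fullness V/(A·l) is kept in the solvable range of
the shape family.

Study-condition defaults, fixed once and documented here:

* five somite stages {6, 8, 10, 12, 14} × 100 central cells, voxel 0.5 µm —
  large enough for stable PCA and trajectory statistics, small enough that
  the full pipeline runs in about a minute per dataset;
* maturation gradient m = s − γ·|p − 0.5| with γ = 4, a linear mid-to-tips
  delay: the anterior tip (|Δp| ≈ 0.42) then lags the trunk by ~1.7 somite
  stages, matching the reported few-stage delay of tip regions;
* multiplicative lognormal size noise, CV 8 %, on l, A and V, plus
  orientation jitter of up to 5° realised as a spin about the AP axis —
  a free 3D tilt of abutting cells would overlap at β = 1 and force
  artificial gaps that bias β upward;
* an intercalation schedule β: 0.45, 0.55, 0.75, 0.9, 1.0 — DV-stacked,
  staggered arrangements converging on the stack-of-coins limit;
* a posterior proliferative fraction shrinking 1.0 → 0.12 across stages,
  with EdU and PhH3 labels drawn only inside it.

Cells are placed single-file along AP. At β = 1 they abut exactly, so group
length equals summed cell lengths. For β < 1, inter-cell gaps are
proportional to adjacent cell lengths with one global factor solved in
closed form so that the *mean* 10-cell window span — the quantity the
intercalation index measures — equals β·n·l̄ exactly; cells whose AP extents
overlap are staggered across DV levels (emulating the multi-layered
pre-intercalation organisation) so labels never collide, and collisions are
a hard error, not a silent overwrite. Anterior cell faces are snapped to the
voxel lattice so noise-free prisms digitise exactly (a 10×5×5 µm cuboid
program yields exactly 250 µm³ and cuboidness 1). With noise off, realised
l_AP and V match the program to better than 2 % at 0.5 µm voxels; the
recovered β is within 0.002 of the schedule.

What the generator does *not* emulate: microscopy (no PSF, no intensity
noise, no segmentation errors), curved or tapering body axes, mechanical
interactions between cells, cell division events (proliferation is a label,
not a lineage process), or gastrulation-stage topologies. Passing tests on
this data therefore demonstrate that the *analysis* recovers known geometric
and temporal structure from idealised segmentations — not that it is robust
to segmentation artefacts in real images.

## Numerical choices and degenerate inputs

* Marching-cubes connectivity uses the classic 256-configuration table
  (stored as generated R source); triangles are oriented so enclosed volume
  is positive. Binary masks put vertices at edge midpoints; smoothed fields
  interpolate along edges.
* The redundancy screen, PCA sign convention, k-means seeding and the
  pipeline's master seed make every stage deterministic; two runs of
  `run_pipeline()` with the same config and seed produce byte-identical CSVs.
* Half-open binning everywhere (AP regions, AP bins, spatial profile), with
  the top endpoint closed into the last bin.
* Degenerate inputs fail loudly: disconnected labels name the label,
  missing stages are listed, empty AP bins merge into their nearest occupied
  neighbour with a warning, β > 1 clips with a warning, stages with fewer
  than 2 cells are skipped in densities.

## Known limitations

* The exact metric formulas of the original acquisition software are not
  public; the definitions above are standard substitutes chosen to match the
  described behaviour (bounding-box fit, surface convolution) and validated
  against closed forms, so absolute values of e.g. cuboidness need not match
  the original software's output.
* Whether the original cross-sectional area is a projection or a mean slice
  is unstated; the projection is used (selectable in principle by computing
  slices from the voxel records).
* The published headline numbers (variance fractions, the 0.94 stage
  correlation, the scenario percentages) derive from 3,796 manually
  segmented cells that are not deposited; this package validates the methods
  on synthetic ground truth instead and makes no claim of reproducing those
  figures.
* Multi-lineage fits are independent per lineage; there is no shrinkage of
  shared curve segments near the bifurcation.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline("run1", list(seed = 1,
                                 simulate = list(cells_per_stage = 60)))
str(res$summary)
```

The summary reports the per-component variance fractions, the
stage–pseudotime Pearson r for the trunk trajectory, the per-stage
intercalation indices and the prism-approximation error; the run directory
contains the feature table, morphospace model and coordinates, pseudotime
table and curves, scenario predictions, proliferation landscape, config echo
with hash, and a timing log. Problem sizes used by the test-suite and
acceptance runs (5 × 100-cell stages, 50-shape mesh oracles, 30-cell
determinism runs) are the package's chosen defaults for a thorough yet quick
desk-scale validation.
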
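# notomorph

Single-cell 3D morphometrics for tissue morphogenesis, built around the
elongating amphioxus notochord.

During notochord development, a loose array of rounded cells reorganises
into a "stack of coins": flattened central cells stacked single-file along
the anteroposterior (AP) axis between dorsal and ventral rows of Müller
cells. `notomorph` quantifies that process from labelled 3D segmentations
(one integer label per cell, physical voxel size):

* **Shape metrics** — volume, isosurface area, axis-aligned and
  object-oriented bounding boxes, moment-ellipsoid axes and orientations,
  transverse cross-sectional area *A*, AP anisotropy *l*<sub>AP</sub>/√A,
  cuboidness *V*/(o₁o₂o₃), sphericity, flatness, ellipticities, nuclear
  displacement.
* **Morphospace** — correlation screening of redundant features, z-scored
  PCA with variance fractions and per-feature contributions, embedding of
  cells into component space.
* **Trajectories** — cluster-guided principal curves: a minimum spanning
  tree over cluster centres (somite stage, AP bins or k-means) seeds an
  iterated project–order–smooth–reparameterise curve fit; pseudotime is the
  scaled arc-length position, with per-stage densities, the stage–pseudotime
  correlation, and 10-bin AP profiles of mean pseudotime.
* **Geometric model** — a mean cell per stage obeying the prism
  approximation *l* ≈ *V*/*A*; counterfactual length scenarios (constant
  volume, isotropic growth *l* ∝ *V*<sup>1/3</sup>, anisotropic growth
  *l* ∝ *V*); the intercalation index β = *l*⁽ⁿ⁾/(n·l̄) and neighbourhood
  predictions *l*⁽ⁿ⁾ = β·n·l̄ separating the contributions of cell shape,
  growth and intercalation to tissue elongation.
* **Proliferation landscapes** — densities of EdU⁺/PhH3⁺ nuclei along the
  normalised AP axis, pooled per stage and scaled to the stage mean length,
  with integrals equal to mean per-embryo counts.
* **Synthetic notochord generator** — parameterised superellipsoid cells
  following branching shape programs (central vs Müller), a mid-to-tips
  maturation gradient, a stage-dependent intercalation schedule and
  posterior-restricted proliferation labels, emitted as labelled volumes
  plus nucleus/annotation/ground-truth tables so every analysis stage is
  testable end to end.

## Worked example

```r
library(notomorph)

res <- run_pipeline("run1", list(seed = 1,
                                 simulate = list(cells_per_stage = 60)))
str(res$summary)
#> List of 7
#>  $ config_hash       : chr "e5f6d56a98a805a374aa3694bf33ccdd"
#>  $ n_cells           : int 594
#>  $ variance_fraction : num [1:5] 0.3794 0.1283 0.1026 0.0845 0.078
#>  $ variance_top      : num 0.773
#>  $ stage_pseudotime_r: num 0.973
#>  $ beta              :List of 5
#>   ..$ 6 : num 0.45
#>   ..$ 8 : num 0.55
#>   ..$ 10: num 0.75
#>   ..$ 12: num 0.9
#>   ..$ 14: num 1
#>  $ eq1_rel_error_max : num 0.329
```

Reading the summary: the first five principal components carry ~78 % of the
shape variance in the synthetic dataset; pseudotime along the trunk
trajectory correlates with somite stage at r ≈ 0.97; the per-stage
intercalation indices recovered from the generated arrangement match the
configured schedule (0.45 → 1.0, the stack-of-coins limit); and the prism
approximation *l* ≈ *V*/*A* is off by up to ~33 % at the bowtie stage —
expected, since flared cells are far from prisms, and reported rather than
absorbed. The run directory holds `features.csv`, `morphospace/`
(model + coordinates), `traj/` (pseudotime + curves), `geo/` (mean-cell
parameters, intercalation series, scenario predictions), `prolif/`
(landscape), `summary.json` and a log.

Lower-level use:

```r
sim   <- generate_notochord(generator_config(seed = 1))
cells <- extract_cells(sim$volumes[["10"]], 0.5,
                       sim$nuclei[sim$nuclei$stage == 10, ])
feats <- feature_table(compute_features(cells), sim$annotations)
model <- fit_morphospace(feats)
print(model)
#> morphospace: 11 features, 180 cells
#> variance explained (%): PC1 29.3, PC2 20.3, PC3 10.9, PC4 10.2, PC5 8.7 | top 5 total 79.3
```

A thin command-line wrapper lives at `inst/scripts/notomorph-cli.R`
(subcommands `run`, `simulate`, `features`).

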
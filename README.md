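# tomoprint

An in-silico pipeline for **context-aware tomographic volumetric
bioprinting**.  In volumetric (tomographic) printing, light projections
from many angles accumulate a 3D dose inside a rotating vial of
photoresin, gelling the resin wherever the dose exceeds a threshold.
When the vat already contains objects — organoid-scale particles,
extruded cell structures, or opaque previously printed parts — the print
should *adapt* to them: channels routed around detected spheres,
sequential parts aligned to what is already there, and projections
re-optimized so opaque occluders do not shadow the print.

`tomoprint` implements that whole loop in software, for researchers who
want to study adaptive-printing algorithms without an instrument:

* **virtual vat** — seeded synthetic scenes (fluorescent spheres of radius
  0.15–0.90 mm, toruses, opaque pillar and cage phantoms, a femur-like
  proxy) and a simulated polar light-sheet scanner in fluorescence and
  reflectance (profilometry) modes;
* **vision** — polar-to-Cartesian point clouds, Otsu foreground isolation,
  DBSCAN feature registration, volume-based radius estimation, PCA pillar
  orientation, spectral classification;
* **geomgen** — generative parametric geometry around detected features:
  spherically wrapped channel networks, grazing channels, strut
  interconnection (kNN + MST + A*), encapsulation shells, tapered torus
  vessel networks with a surface-area constraint, plus SDF voxelization,
  marching-tetrahedra meshing and mesh metrology;
* **align** — trimmed iterative-closest-point rigid registration of a
  reference model to a scanned cloud (the fit `T` is then applied to the
  dependent geometry, `G'_aligned = T G_ref`);
* **tomo** — a telecentric parallel-beam projector/dose pair (exact
  adjoints), occlusion-aware object-space model optimization (OSMO) for
  shadow correction, dose binarization and single-projection (FLight)
  exposure;
* **quality** — Jaccard index, Bhattacharyya coefficient
  (`BC = sum_b sqrt(h_in(b) h_out(b))`), r.m.s. surface error, sphericity
  (`psi = pi^(1/3) (6V)^(2/3) / A`), and benchmark drivers.

The central quantitative result it reproduces in silico: printing an
eight-toothed cog around ten random opaque pillars, OSMO **with** the
scanned occlusion geometry beats OSMO **without** it on every random
configuration — mean Jaccard ≈ 0.74 → 0.95 and mean Bhattacharyya
≈ 0.38 → 0.07 across 12 seeded configurations.

## Worked example

Detect spheres in a synthetic vat, apply the size rule (radius < 0.5 mm
gets a single grazing channel, ≥ 0.5 mm a wrapped network), and check the
realized wall clearance of a wrapped network:

```r
library(tomoprint)

res <- runDemo("conditional-size", seed = 4)
res$report
#>   id    radius          rule
#> 0  0 0.3265801 grazing-small
#> 1  1 0.7254780 wrapped-large

wrap <- runDemo("wrap-spheres", seed = 1)
wrap$report
#>   feature    radius clearance
#> 1       0 0.7127729 0.2995922
#> 2       1 0.6070117 0.2995596
#> 3       2 0.5850070 0.2995300
```

The detected radii are cluster-volume estimates from the simulated
half-sweep scan (true radii 0.3 and 0.7 mm in the first demo), the rule
column shows the size-conditional dispatch, and the clearances confirm the
0.3-mm stand-off contract between each feature's surface and its generated
channel wall (measured on 25-µm meshes, so ±1 voxel).

A six-seed shadow-correction run:

```r
rep <- shadowBenchmark(nReps = 6, seeds = 1001:1006)
reportAggregate(rep)
#>           arm n jaccard_mean  jaccard_sd bhattacharyya_mean bhattacharyya_sd
#> 1   corrected 6    0.9550523 0.007410470         0.06844119       0.01222213
#> 2 uncorrected 6    0.7431562 0.008271628         0.38076497       0.01951606
```

Ten demo scenarios (`demoCatalog()`) cover the full workflow, from
wrapped-network generation to femur/cartilage auto-alignment and FLight
exposure; `runPipeline(list(demo = "pillar-shadow", seed = 1), "out/")`
writes every artifact (scene YAML, features JSON, metric CSV/JSON, log)
with provenance.  A thin CLI lives at `inst/cli/tomoprint`.

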
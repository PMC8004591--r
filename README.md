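# leafMorph

Automatic measurement of typical leaf samples on triangle meshes of potted
plants, as produced by hand-held 3D laser scanners.

Plant phenotyping pipelines need per-leaf morphological traits, but a raw
scanner mesh contains the table, the pot, newborn and damaged leaves, and
partially scanned foliage alongside the leaves one actually wants to
measure. leafMorph implements a fully automatic pipeline for broad
elliptical leaves (pothos and similar species):

1. **Non-plant removal** — RANSAC detection of the table plane, then removal
   of every face within a 100 mm buffer above it (table, pot, soil).
2. **Multi-level region-growing segmentation** — clusters grow from
   low-curvature seeds under a smoothness threshold ε_a and a curvature
   threshold ε_b that adapt to the mesh's own statistics: starting at
   ε_a = 1.5ς, ε_b = 1.5ρ (ς, ρ = mean smoothness and curvature) and
   shrinking by 0.05 ς, 0.05 ρ per level, at most 30 levels.
3. **Typical-leaf selection** — two PCA-weighted shape models are refitted
   at every level: a size model F(X) = Σ aᵢ (X₀ᵢ − X̄₀ᵢ)/X̄₀ᵢ over area,
   perimeter, length and width, and an architecture model G(X) = Σ bⱼ X₁ⱼ
   over their six ratios, with weights = PCA variance contribution rates.
   A cluster is a typical leaf sample iff 0.25 < 1 + F(X) < 1.25 and
   0.25 Ḡ < G(X) < 1.25 Ḡ.
4. **Trait measurement** — per leaf: area (triangle sum), perimeter
   (boundary length), length (longest refined surface geodesic along the
   first principal axis; Dijkstra seed + corridor unfolding/funnel + surface
   relaxation), width (widest on-surface transect perpendicular to the
   length path), and the six ratios.

The package also provides the accuracy statistics used to validate such
pipelines (scanning/segmentation accuracy ratios, modeling efficiency EF,
RMSE, MAPE) and a procedural generator of scanner-like plant scenes with a
ground-truth ledger, so the whole pipeline is testable without scanner
hardware. See the vignette `vignettes/leaf-measurement-methods.Rmd` for the
method, its assumptions and its limitations.

## Worked example

```r
library(leafMorph)

# a synthetic scanner scene: table + pot + six pothos-like leaves
spec  <- PlantSceneSpec(nLeaves = 6, rngSeed = 7)
scene <- generatePlantScene(spec)
writeMesh(scene$mesh, "plant.ply")

res <- runPipeline("plant.ply", outputDir = "out")
res$report
#> SegmentationReport: 6 typical leaves, 0 rejected, 1 levels
round(res$traits[, 1:5], 2)
#>   leaf_id   s_mm2   c_mm  l_mm  w_mm
#> 1       1 2216.04 173.11 66.87 42.36
#> 2       2 2016.59 165.30 63.80 40.38
#> 3       3 2046.04 166.42 64.30 40.69
#> 4       4 2062.52 167.15 64.49 40.82
#> 5       5 2026.71 165.64 63.99 40.45
#> 6       6 2031.16 165.94 64.06 40.46
```

All six leaves are found in one segmentation level; the trait table reports
area (mm²), perimeter (mm), length (mm), width (mm) and — in the full table
— the six ratio traits x11…x16. Matching the clusters back against the
scene's ground-truth ledger confirms every typical leaf was recovered:

```r
matchLedger(res$report, res$plantMesh, scene$ledger)$recall
#> [1] 1
```

The evaluation helpers work on counts and trait tables. For example, the
bundled benchmark table of per-plant leaf counts (twelve pothos plants in
four canopy-occlusion groups) gives the overall accuracy ratios:

```r
counts <- segmentationCounts()
accuracyRatios(sum(counts$n1), sum(counts$n2), sum(counts$n3))
#> r_scan r_seg1 r_seg2
#>  94.02  93.18  87.61
```

i.e. 94.02% of manually selected typical leaves were well scanned, and
87.61% were selected fully automatically.

A thin command-line wrapper with `simulate`, `segment`, `traits`,
`evaluate` and `run` subcommands is installed at
`inst/scripts/leafmorph`.

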
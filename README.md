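# VoroClust

Voronoi tessellation and statistical cluster segmentation for
single-molecule localization microscopy (SMLM) point clouds, in 2D and 3D.

SMLM experiments produce tables of molecular coordinates (nanometer
units, often millions of rows) rather than images. VoroClust quantifies
such point clouds through their Voronoi tessellation: each localization
owns one convex cell whose size (area in 2D, volume in 3D) is the inverse
of the local density. The package is aimed at microscopists and image
analysts who need density-based segmentation of localization data with a
statistically defined, parameter-free threshold.

## What it computes

**Tessellation.** Every Voronoi cell is built independently: the Delaunay
triangulation supplies each point's *one-ring* (all points sharing a
simplex with it), which by Voronoi/Delaunay duality contains every
facet-contributing neighbour; the cell is then the intersection of the
bisector half-spaces with those neighbours, clipped to a bounding box.
This per-cell scheme needs no global mesh, handles the extreme density
contrast of SMLM data (no `k` to choose), and scales to millions of
localizations on one core. Cells cut by the dataset bounding volume are
flagged as border cells and excluded from all statistics to prevent edge
effects.

**Cluster segmentation** (the ClusterVisu approach). With normalized cell
sizes `y = S / <S>` (mean over non-border cells), clustered data show an
excess of small cells over a spatially random null. The threshold `y*` is
the intersection of the experimental cell-size distribution with the null
distribution; cells with `S < y* <S>` are selected and grouped into
clusters by Voronoi facet adjacency. Two interchangeable nulls are
provided:

- `monteCarloNull()` — the cell-size distributions of repeated uniform
  simulations with the same localization count and volume (bin-wise mean
  plus envelope);
- `analyticalNull()` — the closed-form Poisson–Voronoi gamma
  approximations, at no simulation cost:

  ```
  f_2D(y) = (343/15) sqrt(7/(2*pi)) y^(5/2) exp(-7y/2)     (Gamma, shape = rate = 7/2)
  f_3D(y) = (3125/24) y^4 exp(-5y)                         (Gamma, shape = rate = 5)
  ```

A minimal density-factor segmentation (`segmentByDensityFactor()`,
selecting cells with density at least `alpha` times the average) and a
synthetic localization simulator with ground-truth labels
(`simulateClustered()`, `simulateUniform()`) round out the pipeline.

## Worked example

```r
library(VoroClust)

cfg  <- clusterSimConfig(seed = 42)   # 20 Gaussian clusters, sigma 50 nm,
locs <- simulateClustered(cfg)        # 500 locs each + 10% background,
locs                                  # in a 2 x 2 x 2 um^3 volume
#> LocalizationSet: 11111 localizations in 3D
#>   bounds extent (nm): 2000.0 x 2000.0 x 2000.0
#>   extras: label

vd <- buildVoronoi(locs)
vd
#> VoronoiDiagram: 11111 cells (3D), 5.8% border
#>   mean non-border cell size: 442522 nm^3

cr <- clusterVisu(vd, null = "analytical")
cr
#> ClusteringResult: 20 clusters (analytical null, y* = 0.2897)
#>   localizations in clusters: 8605; median volume: 8.99525e+06
head(cr@clusters, 3)
#>   id nLocs  volume barycenter.x barycenter.y barycenter.z
#> 1  1   431 9272017     1700.093    1745.0305     639.3902
#> 2  2   434 8809882     1565.084    1243.9301    1033.9205
#> 3  3   434 9230556     1403.568     375.8842    1264.4729
```

All 20 planted clusters are recovered; `y* = 0.29` says cells smaller
than 0.29 times the mean cell volume (i.e. local density at least ~3.5x
the average) form the clusters. The Monte-Carlo null gives the same
segmentation within a few percent, at 50 simulations' cost:

```r
crMC <- clusterVisu(vd, null = "monte_carlo", nSims = 50, seed = 1)
crMC@threshold
#> VoronoiThreshold (monte_carlo): y* = 0.3005, s* = 132989
matchClusters(crMC, cr)$meanVolumeDiff
#> [1] 1.94
```

A command-line driver wraps the same pipeline
(`inst/scripts/voroclust.R`, subcommands `simulate`, `tessellate`,
`cluster`, `nullcheck`), reading options from JSON/YAML config files
and echoing the effective configuration next to its outputs.

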
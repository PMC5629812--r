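# landconnect

Multi-species landscape genetics in R: population-graph genetic networks,
circuit-theory connectivity surfaces, and the regression that ties them
together.

The package is for landscape geneticists and connectivity modelers who have
(a) codominant microsatellite genotypes sampled at many sites and (b) a
resistance raster for the intervening landscape, and who want node-based —
not pairwise — answers to "where does gene flow track the landscape?". It
also ships a seedable synthetic-data generator so the entire chain can be
exercised, tested and benchmarked without field data.

## What it computes

**Genetic side.** Individuals with more than 35% missing allele calls are
removed (strict inequality). Genotypes are encoded as within-individual
allele frequencies (0 / 0.5 / 1 per allele column), site centroids give the
among-population covariance `C` and distance
`D_ij = C_ii + C_jj − 2C_ij`. The saturated site network weighted by `D` is
pruned by conditional independence: an edge survives iff its edge-exclusion
deviance

    EED_ij = −N · ln(1 − r²_ij·rest) > χ²₁(1 − α),   α = 0.05

where `r_ij·rest` is the partial correlation from the (pseudo)inverse of
`cov2cor(C)`. Shortest paths on the pruned graph are the conditional
genetic distance (cGD); a node's genetic connectivity is its mean inverse
retained edge weight, z-scored within species.

**Landscape side.** The resistance raster (three cost classes 10 / 100 /
1000 at 100 m cells) becomes an electrical lattice; sparse Cholesky solves
of the graph Laplacian give voltages, effective resistance
`R_eff = Δv / I`, and per-cell current density. The omnidirectional map
averages current over random perimeter source/ground pairs placed outside
the study area (no node-placement bias) and is standardized to mean zero.
A circular-neighborhood diagnostic places 5 focal nodes 72° apart, inset
300 m from the window boundary, and compares mean `R_eff` over the five
next-nearest pairs with mean window current density.

**Linkage.** Buffers at three radii around each node yield 12 covariates
(mean/SD × cost/current × 3 radii); PCA retains 4 components and OLS models
the standardized connectivity on x, y, sample size and the PC scores, for
the full node set and per species group.

## Worked example

The `analysis/` directory is a numbered workflow over a 60×60 synthetic
landscape with two simulated species (12 sites each). Run it from the
repository root:

```sh
Rscript analysis/01_simulate.R      # landscape + genotypes
Rscript analysis/02_popgraph.R      # filter, prune, cGD, node connectivity
Rscript analysis/03_circuit_map.R   # omnidirectional current map
Rscript analysis/04_covariates.R    # buffered covariates
Rscript analysis/05_inference.R     # PCA + OLS
Rscript analysis/06_neighborhoods.R # circular-window diagnostic
Rscript analysis/07_recovery.R      # replicated recovery experiment
```

Selected output from a run with the default seed:

```
north_sp: kept 35 of 66 edges; mean edge weight 0.078, mean inverse 14.323
south_sp: kept 28 of 66 edges; mean edge weight 0.052, mean inverse 21.790
current map: study-area mean 5.57e-19 (standardized), raw mean 0.0236
mean cost vs mean current correlations: 9 of 9 negative (range -0.87 to -0.48)
PCA: first 4 PCs explain 47.9/23.9/9.7/6.6% (cumulative 88.2%)
full model: n=24, F=4.68 (df 7,16), adj R2=0.528; CI excludes 0: PC1
radius 2000 m: r(current, resistance) = +0.750 over 24 nodes
```

Reading this: pruning keeps roughly half the saturated edges; the
standardized current map averages to zero by construction; buffered cost
and current are strongly negatively correlated at every radius (current
concentrates in low-cost cells), which is why the covariates go through a
PCA — four components carry ~88% of the variance; and the full regression
finds the first (cost/current) component predictive of node connectivity.
The neighborhood diagnostic shows window-mean current rising with window
effective resistance across the nodes of this heterogeneous landscape.

Tables land in `results/` (`node_connectivity.csv`, `node_records.csv`,
`pca_loadings.csv`, `regression.csv`, `neighborhoods.csv`, ...), graphs as
GraphML, rasters as ESRI ASCII grids. `run_pipeline()` performs the same
chain from a single YAML config for one species.

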
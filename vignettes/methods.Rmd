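---
title: "Methods: population graphs, circuit theory, and the landscape regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population graphs, circuit theory, and the landscape regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landconnect)
```

# Overview

`landconnect` links node-based estimates of gene flow to landscape
structure. The chain has five stages:

1. **Genetics.** Codominant microsatellite genotypes are filtered
   (individuals with more than 35% missing allele calls are removed; the
   inequality is strict, so 35.0% exactly is retained), encoded as
   within-individual allele frequencies, and summarized as an
   among-population covariance matrix `C` and distance matrix
   `D` with `D_ij = C_ii + C_jj - 2 C_ij`.
2. **Population graph.** Sites are nodes of a saturated network weighted by
   `D`. Edges are pruned by conditional independence: with `R = cov2cor(C)`
   and precision `P`, the partial correlation of an edge given all other
   nodes is `r_ij = -P_ij / sqrt(P_ii P_jj)` and its edge-exclusion deviance
   is `EED = -N log(1 - r_ij^2)` for `N` genotyped individuals; an edge
   survives iff `EED` exceeds the chi-square(1) critical value at `alpha`
   (3.841 at the default `alpha = 0.05`). Conditional genetic distance (cGD)
   is the shortest-path length along the pruned network, and a node's
   genetic connectivity is the mean of `1/weight` over its retained incident
   edges, z-scored within species so species sit on one scale.
3. **Circuit.** A resistance raster (costs 10 / 100 / 1000 at 100 m
   resolution for the three-class scheme: permeable, semi-permeable,
   high-cost cover) becomes an electrical lattice: cells are nodes, adjacent
   cells are resistors with the arithmetic mean of the two cell costs.
   Solving the graph Laplacian gives pairwise voltages, effective
   resistance `R_eff = (v_s - v_g)/I`, and per-cell current density (half
   the sum of absolute incident edge currents). The omnidirectional map
   averages current density over many random source/ground pairs placed on
   the perimeter of a padded copy of the raster — terminals stay outside
   the study area, which removes node-placement bias — and is standardized
   to mean zero over the study area.
4. **Covariates.** Each genetic node is buffered at three radii; the mean
   and population SD of cost and of current density in each buffer give 12
   landscape covariates per node.
5. **Inference.** PCA of the covariate correlation matrix (the covariates
   are strongly inter-correlated by construction), retention of the first 4
   PCs, and OLS of the standardized node connectivity on projected x, y,
   sample size, and the PC scores, for the full node set and for
   species-group subsets.

A synthetic-data generator makes the whole chain testable end to end
without field data, and a replicated recovery experiment
(`recovery_experiment()`) probes which landscape signals the regression
recovers.

# The synthetic generator

`generate_landscape()` thresholds a smoothed Gaussian random field at
quantiles: the lowest-cost class covers `habitat_fraction` of cells and the
remainder splits between the middle and high classes (50/50 by default; the
field gives no guidance on the mixture, so an uninformative even split is
used). `clustering` is the Gaussian smoothing length in cells and directly
controls spatial autocorrelation (Moran's I rises monotonically with it —
tested). Smoothing uses FFT convolution with periodic wrap-around; at the
landscape sizes used here the wrap has no visible effect beyond a few cells
of the border.

`simulate_genotypes()` draws ancestral allele frequencies per locus from a
flat Dirichlet, then site frequencies from a Dirichlet centered on the
ancestral vector with concentration `1 / (drift_scale x R_site)`, where
`R_site` is the site's mean effective resistance to all other sites on the
supplied landscape. Because the variance of a Dirichlet draw scales as
`1/(concentration + 1)`, the product `drift_scale x R_eff` is approximately
the expected among-site F_ST. Typical synthetic landscapes here have
inter-site effective resistances of roughly 40–700 ohms, so the default
`drift_scale = 5e-4` spans F_ST of about 0.05–0.3 — the range usually seen
in microsatellite studies of vertebrates at regional scales — and the
"strong drift" setting used in the recovery experiment (1e-3) roughly
doubles it. `drift_scale = 0` reproduces the ancestral frequencies exactly
at every site (tested), giving a clean null.

What the generator emulates: multi-site sampling with uneven sample sizes,
missing allele calls, and genetic divergence that increases monotonically
with landscape effective resistance (the pooled correlation between
inter-site `R_eff` and genetic distance is strongly positive under drift —
recomputed by `scripts/acceptance.R`). What it does **not** emulate:
mutation (no stepwise or infinite-allele process), coalescent genealogy,
sex-biased dispersal, water/NoData barriers, and within-site structure. A
passing suite therefore shows the machinery is correct and that the
regression recovers resistance-driven divergence; it does not show that any
particular empirical system behaves this way.

# Numerical choices

* **Solver.** The grounded Laplacian is factorized once per landscape with
  a sparse Cholesky decomposition (`Matrix::Cholesky`) and the factor is
  reused for every terminal pair, so a 64-pair omnidirectional map costs
  one factorization plus 64 triangular solves. Direct solves are exact to
  machine precision at these problem sizes; a residual guard still rejects
  solutions above 1e-8 relative. The dense pseudoinverse oracle
  (`R = L+_ss + L+_gg - 2 L+_sg`) agrees to ~1e-13 in the tests.
* **Precision matrix for pruning.** The among-population covariance is
  grand-centered and thus rank-deficient by exactly one; a plain or ridged
  inverse of its correlation matrix explodes along the null direction and
  drives every partial correlation to ±1. The precision is therefore the
  eigen-pseudoinverse with the null space excluded (rank logged). This is
  the behavior the Gaussian-graphical-model formulation needs, and the
  identity-covariance case (all partials zero, empty edge set) and a dense
  oracle verify it.
* **Edge resistance** is the arithmetic mean of the two cell costs
  (diagonal neighbors, when enabled, scale by sqrt(2)); 4-neighbor
  connectivity is the default because its analytic test circuits (series
  chains, parallel rings) are exact by hand.
* **Zero genetic distances** between distinct sites are clamped to
  `1e-9 x max(D)` with a warning so shortest paths stay defined.
* **Buffer membership** is center-in-circle — unambiguous and
  brute-force-checkable — and buffer SDs are population SDs (the buffer is
  the whole population of cells, not a sample).
* **Perimeter pairs** for the omnidirectional map are drawn without
  replacement and forced at least 90 degrees apart around the perimeter, so
  no pair short-circuits along the pad. The pad cost defaults to the mean
  study-area cost (a neutral medium); pad width is 8 cells by default.
* **Focal rings.** The five focal nodes of a circular neighborhood sit 72
  degrees apart on the circle inset 300 m from the boundary, starting at a
  seeded random angle; "next-nearest" pairing is (i, i+2 mod 5), giving
  exactly five pairs. Nearest-cell snapping of the ring perturbs chord
  lengths by about half a cell, which bounds the spread of the five pair
  resistances on a uniform landscape at roughly `cell/radius` (~2–3% at the
  radii used in the tests).
* **PC sign convention:** each loading column is flipped so its
  largest-magnitude element is positive; signs are otherwise arbitrary.
* **Confidence intervals** use `slope ± t(0.975, df) x SE`, not 1.96, since
  node counts are small.

# Open design decisions

* **Incident edges vs all pairs.** Node connectivity uses retained incident
  edges by default; the per-species mean of `1/weight` then sits near the
  reciprocal of the mean edge weight, and Jensen's inequality
  (`mean(1/w) >= 1/mean(w)`) holds by construction. An all-pairs variant
  over `1/cGD` is available (`node_connectivity(..., method = "allpairs")`).
* **Radii are radii.** Buffer sizes are interpreted as radii; a
  configuration switch (`as_diameter`) halves them for workflows that
  specify diameters instead.
* **Neighborhood current source.** The window-mean current density defaults
  to the five pairwise solves confined to the window (self-contained); a
  precomputed omnidirectional map can be sampled instead
  (`current_map = ...`).
* **Number of perimeter pairs.** 64 by default: on uniform landscapes the
  interior density surface is flat to a CV of well under 0.2 at that count.

# What the recovery experiment shows — and what it cannot

Within a synthetic landscape, the omnidirectional current map concentrates
in low-cost cells: buffer mean current and buffer mean cost correlate
strongly negatively (all 9 cross-radius comparisons negative in the demo
workflow), and nodes on that conductive backbone are also the
well-connected ones. Consequently the marginal — and usually also the
partial — effect of buffered current density on node connectivity is
**positive or null** in these simulations: the generator ties divergence to
movement resistance, and buffered current flags the low-resistance
backbone. A negative current–connectivity effect, by contrast, requires a
mechanism this generator deliberately lacks: gene flow tracking habitat
amount (settlement) rather than movement resistance, combined with a
geography that forces current through fragmented regions instead of letting
it route around them. The stratified summary that
`recovery_experiment()` emits (fraction of replicates with a negative
current-PC effect, per habitat stratum) therefore hovers around one half
and should be read as "no consistent direction", not as support for either
sign; the corresponding acceptance check is expected to fail and is left
failing rather than weakened. The null half of the experiment behaves as
designed: with `drift_scale = 0`, predictors exclude zero at close to the
nominal 5%.

Relatedly, the across-landscape neighborhood diagnostic (one circular
window per landscape, habitat fraction swept 0.1–0.9) shows an essentially
flat relation between window-mean current density and effective resistance:
with unit-current injection the mean |current| over a fixed window is nearly
invariant to the landscape's composition (it responds only to path
geometry), while `R_eff` tracks absolute cost. Replicated measurements put
the expected window-mean current at 0.036–0.039 across the full habitat
sweep while `R_eff` varies five-fold. The *within-landscape, across-node*
version of the same diagnostic — windows at different places in one
heterogeneous landscape — does show a positive correlation at the larger
radii in the demo workflow, because there window composition and
configuration vary together.

# Problem sizes

The test suite and acceptance script use landscapes of 18x18 to 60x60
cells (100 m cells, i.e. 1.8–6 km extents), 4–14 sites per species,
8–12 loci with 6–8 alleles, 10–30 individuals per site, 64 perimeter pairs,
and buffer radii scaled to the landscape (400–2000 m) the way multi-km
radii relate to a provincial extent. These sizes keep a full
pipeline replicate at about two seconds while leaving every statistical
mechanism (drift, pruning, funneling, PCA collinearity) active; all of them
are configuration, not code limits — the solver guard admits rasters up to
4e6 cells.

# Known limitations

* No mutation model, so long-time-scale divergence is understated relative
  to drift.
* Raster I/O is ESRI ASCII grid only; attach CRS metadata via the `crs`
  tag.
* Very large rasters need tiling, which is out of scope; the cell-count
  guard errors instead.
* Genepop input assumes 2- or 3-digit allele codes and one comma per
  individual line.
* The pipeline models one species per genotype table; the demo workflow
  shows the per-species loop and the pooled regression.
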
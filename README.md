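# betascape

Partitioning landscape beta-diversity into niche and stochastic-dispersal
components.

`betascape` is an analysis workflow for spatial community ecologists who
want to know how much of the compositional turnover (beta-diversity) of a
forested landscape is structured by environmental niches and how much by
dispersal-limited stochastic dynamics. It implements, end to end:

- **Remote beta-diversity estimation** — quality filtering (NDVI >= 0.8,
  solar zenith <= 50°), water-band exclusion and spectral resampling,
  L2 brightness normalisation, k-means "spectral species" clustering, and
  gridded pairwise Bray-Curtis dissimilarity
  `d_jk = Σ_i |x_ij − x_ik| / Σ_i (x_ij + x_ik)` between 1-ha cells with
  at least 25% spectral coverage.
- **Spatial structure** — Mantel tests with permutation inference and
  Mantel correlograms with Sturges-truncated distance classes and
  500-replicate bootstrap confidence intervals.
- **Niche quantification** — generalised dissimilarity models (GDM):
  monotone I-spline regression of dissimilarity on geographic distance and
  environmental differences under the link `d = 1 − exp(−η)`, with
  non-negative coefficients fitted by iteratively reweighted non-negative
  least squares on the binomial deviance; deviance partitioning into
  distance-only (D), environment-only (E) and spatially autocorrelated
  environment (D×E); permutation variable importance; forest types as
  orthogonal contrasts. Terrain predictors (slope, TRI, TPI, mean
  elevation, canopy height) are computed in-package.
- **Neutral reconstruction** — a spatially explicit neutral coalescent
  (Rcpp) with point speciation ν and fat-tailed dispersal kernels
  `f(r) ∝ r (1 + r²/(τσ²))^(−(τ+2)/2)`, including a forest-type-aware
  variant with per-type kernels and a Bernoulli(m) penalty on cross-type
  dispersal, and a well-mixed mode with an exact Ewens-formula oracle.
- **Inference loop** — sweep (σ, τ, ν) grids through the simulator, fit
  distance-only GDMs to each virtual census, match the resulting
  I-splines against empirical target splines by RMSE, and test whether a
  single parameter set reconstructs every forest type at once.

A synthetic-data module (`gen_landscape`, `gen_community`, `gen_spectra`,
`gen_cube`) generates all inputs with known ground truth, so the entire
workflow runs without external data.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
30 × 30-cell landscape with three forest types and 25 species
(`Rscript analysis/01_simulate_landscape.R`, then 02 … 06). Output from a
run of scripts 02 and 04:

```
Pixels passing quality filters: 12755 / 14400
Cells retained at >= 25% coverage: 900 ( 0 dropped )
Spectral vs true beta-diversity: Mantel r = 0.897 (p = 0.0010)

Forest-type affiliation explains 75.6% of beta-diversity
  type 1: D 0.0% | E 13.1% | DxE 0.1% | total 13.2%
  type 2: D 0.0% | E 19.3% | DxE 0.2% | total 19.5%
  type 3: D 0.6% | E 25.1% | DxE 1.6% | total 27.2%
```

Reading these numbers: the spectral-species Bray-Curtis matrix reproduces
the true community dissimilarity almost perfectly (Mantel r = 0.90), so
the image is a faithful beta-diversity survey. The synthetic community was
generated with strong type affinities and elevation optima but only
short-range dispersal clumping — and the partition recovers exactly that:
forest-type membership dominates (75.6% between types), the continuous
environment explains 13–25% within types, and the distance-only component
is near zero. Script 03 locates significant compositional autocorrelation
out to ~3.4 km, script 05 sweeps 24 neutral parameter sets, and script 06
matches their I-splines against each forest type's empirical splines.

The same machinery is available directly:

```r
library(betascape)
L     <- gen_landscape(30, 30, n_types = 3, seed = 101)
truth <- gen_community(L, n_species = 25, niche_strength = 2,
                       aggregation = 2, px_per_cell = 4, seed = 102)
cube  <- gen_cube(truth, gen_spectra(25, seed = 103), noise_sd = 0.01,
                  invalid_fraction = 0.05, seed = 104)
comm  <- spectral_species(cube, k = 25, seed = 201)$community
pairs <- build_site_pairs(bray_curtis(comm),
                          cell_environment(L)[as.integer(sub("cell_", "",
                            comm$ids)), ])
gdm_partition(pairs, c("elevation", "tri", "tch"))
```

## Package layout

```
R/              landscape/community/cube generators, spectral pipeline,
                terrain metrics, diversity statistics, I-spline GDM,
                coalescent interface, inference loop, pipeline orchestrator
src/            the backwards-in-time coalescent (Rcpp)
analysis/       numbered narrative drivers for the full study
tests/testthat/ unit, property and acceptance suites
vignettes/      methods vignette (models, assumptions, design choices)
scripts/        acceptance.R (see above)
```
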
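---
title: "Partitioning landscape beta-diversity into niche and dispersal components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning landscape beta-diversity into niche and dispersal components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betascape)
```

## The scientific problem

Tropical tree communities turn over in space (beta-diversity) for two
reasons that are hard to separate: environmental filtering sorts species
along topographic and edaphic niche axes, and stochastic, dispersal-limited
recruitment creates spatial clumping even among ecologically equivalent
species. Both mechanisms produce spatially autocorrelated composition, so
pattern alone does not identify process. `betascape` implements a workflow
that confronts the two mechanisms explicitly:

1. estimate wall-to-wall beta-diversity from a hyperspectral image by
   clustering pixel spectra into "spectral species" and computing pairwise
   Bray-Curtis dissimilarity between 1-ha cells;
2. describe its spatial structure with Mantel correlograms;
3. partition the dissimilarity deviance into components uniquely explained
   by geographic distance (D), uniquely by the environment (E) and by their
   spatially autocorrelated overlap (DxE) using generalised dissimilarity
   models (GDMs);
4. ask whether the distance-driven part can be reproduced by a spatially
   explicit neutral model: simulate communities with a backwards-in-time
   coalescent under fat-tailed dispersal kernels, fit the same
   distance-only GDM to each virtual census, and select the dispersal and
   speciation parameters whose I-spline best matches the empirical one.

Because the original airborne and plot data are large external archives,
the package ships a synthetic-data module that generates every input with
known ground truth; all tests and the acceptance script run end-to-end on
those synthetic inputs.

## Models and their assumptions

### Bray-Curtis dissimilarity and the spectral proxy

For sites $j,k$ with abundances $x_{ij}$,
$d_{jk} = \sum_i |x_{ij}-x_{ik}| \,/\, \sum_i (x_{ij}+x_{ik})$.
In the spectral pipeline the "taxa" are k-means clusters of
brightness-normalised pixel spectra. Abundances are raw pixel counts, not
per-cell proportions: the dissimilarity of the defining formula acts on
counts, and the minimum-coverage rule (below) keeps count totals roughly
comparable between cells. Spectral clusters are proxies, not species; the
pipeline-recovery tests show the proxy preserves the Bray-Curtis structure
on clean scenes, not that it resolves taxonomy.

Quality control mirrors standard imaging-spectroscopy practice: pixels
with NDVI < 0.8 (computed from the bands nearest 660 and 800 nm, since
exact band positions are sensor-specific) or solar zenith angle > 50
degrees are discarded; bands below 420 nm, above 2400 nm and inside the
1350-1480 / 1780-2032 nm water-vapour windows are dropped; remaining bands
are averaged in groups (3 in the VNIR, 2 in the SWIR) to raise
signal-to-noise; each pixel is divided by its L2 norm (brightness
normalisation -- the standard convention for this step), so clustering acts
on spectral shape rather than albedo. Cells with less than 25% valid
pixels are excluded from the community matrix.

### Mantel statistics

The Mantel correlation between two distance matrices is the Pearson
correlation of their upper triangles; significance comes from permuting
site labels (rows and columns jointly), which respects the
non-independence of the pairs. Random permutations use the add-one
p-value estimator $(1 + \#\{|r^*| \ge |r|\})/(n_{perm}+1)$ -- never zero,
and unbiased in the usual sense; exact enumeration is available for tiny
fixtures. The correlogram splits geographic distance into equal-width
classes -- their number follows Sturges' rule
$\lceil 1+\log_2(\text{pairs})\rceil$, the convention for truncating
correlograms -- and computes one Mantel correlation per class against the
class-membership indicator. The sign is chosen so that positive values
mean "sites this far apart are more similar than expected by chance"
(the raw correlation with a 0/1 within-class coding is negated).
Confidence intervals resample *sites* with replacement (500 replicates by
default) and take percentile 2.5/97.5 bounds; pairs formed by a site
drawn twice have zero geographic distance and are excluded.

### Generalised dissimilarity models

Predicted dissimilarity is $\hat d = 1-\exp(-\eta)$ with
$\eta = a_0 + \sum_p |f_p(x_{p2}) - f_p(x_{p1})|$, each $f_p$ a
non-negative combination of monotone I-splines; geographic distance enters
as a single monotone spline of the pair distance. Three I-splines per
predictor with knots at the 0/50/100th percentiles are the default (the
reference GDM implementation's choice); the basis is built from order-2
M-splines, whose integrals are the familiar quadratic I-splines -- with
three knots this yields exactly three splines per predictor. When
percentile knots tie (two-valued contrast predictors), evenly spaced knots
over the range are used instead.

Coefficients (and the intercept) are estimated under non-negativity by
iteratively reweighted non-negative least squares on the binomial-type
deviance, with step halving whenever an update fails to decrease the
deviance; convergence is declared when the largest coefficient change
drops below 1e-8 (at most 200 iterations). Observed $d = 1$ is truncated
to $1-10^{-9}$ to keep the objective finite; percent deviance explained is
$100(1 - \text{dev}_{model}/\text{dev}_{null})$ against the intercept-only
model, clamped to $[0, 100]$ for reporting.

The partition fits three models -- distance-only, environment-only, full --
and reports unique D = full - explained(E), unique E = full -
explained(D), and shared DxE = explained(D) + explained(E) - full. A
negative component (the separate fits can overlap more than they add) is
clamped to zero and the others rescaled so the three still sum to the full
model's explained deviance, matching the reporting convention of zero
shared fractions. Forest type enters between-type models as orthogonal
Helmert contrasts. Variable importance permutes one predictor's
site-level values at a time and *refits* the model (50 permutations by
default); refitting was chosen over re-evaluating the fixed coefficients
because the non-negativity constraint makes frozen coefficients
systematically pessimistic for the permuted predictor.

### The spatial neutral coalescent

Virtual censuses come from a backwards-in-time coalescent: one lineage per
sampled individual; each event picks an active lineage uniformly at
random; with probability $\nu$ it speciates (all its descendants get a
fresh species), otherwise it moves to a parent drawn through its dispersal
kernel and a uniform slot within the target cell's density, coalescing
with any lineage already in that slot. A sole surviving lineage is the
most recent common ancestor of its descendants and founds the final
species. Event order is uniform over active lineages, which is equivalent
to a continuous-time embedding up to a time rescaling the equilibrium
census does not depend on.

The dispersal kernel is a 2D Student-t-type family with radial density
$f(r) \propto r\,(1+r^2/(\tau\sigma^2))^{-(\tau+2)/2}$: $\sigma$ sets the
scale (conceptually the mean dispersal distance) and $\tau$ the fatness of
the tail; as $\tau \to \infty$ it converges to the Rayleigh/Gaussian
kernel of scale $\sigma$ (mean $\sigma\sqrt{\pi/2}$), which supplies an
analytic oracle for the sampler. The closed-form CDF
$F(r) = 1-(1+r^2/(\tau\sigma^2))^{-\tau/2}$ is inverted directly. The
kernel form is a swappable strategy object; this family was chosen for its
interpretable parameters and testable limits. The landscape is closed:
displacements falling outside are redrawn (no torus), because the study
arena is a bounded reserve.

The forest-type-aware variant keeps within-type dynamics strictly neutral
but penalises cross-type dispersal: a proposed parent cell in a different
forest type than the lineage's current cell is accepted with probability
$m$ and otherwise redrawn. $m = 1$ consumes no extra random draws, so it
reproduces the naive code path bit-for-bit on a shared seed (a tested
identity); $m = 0$ confines every lineage to its type, which with point
speciation forces Bray-Curtis of 1 between types (also tested exactly).
Each forest type can carry its own kernel. The well-mixed `"global"` mode
draws the parent uniformly from the other $J-1$ individuals, and its mean
richness is checked against the Ewens sampling formula
$E[S]=\sum_{i=0}^{J-1} \theta/(\theta+i)$, $\theta = \nu(J-1)/(1-\nu)$.

### The inference loop

`sweep_splines()` runs one census per parameter set (replicates are
configurable to quantify Monte-Carlo error), fits the distance-only GDM
and evaluates its I-spline on a common grid of 100 distances from zero to
the maximum sampled pair distance. `match_splines()` scores candidates by
root-mean-square difference on that grid (maximum absolute difference is
available) and breaks exact ties towards smaller $\nu$, then $\sigma$,
then $\tau$. `consistency_test()` reports whether one candidate stays
within 1.25x the per-type best score for every forest type at once -- the
diagnostic for dispersal acting independently of niche structure.

## The synthetic-data generator

`gen_landscape()` builds covariates by FFT circulant-embedding synthesis
of Gaussian random fields with exponential correlation; the `autocorr_range`
argument is the practical range (95% of the semivariogram sill). Forest
types come from thresholding a further field at equal-area quantiles
(contiguous-tending mosaics) or from deterministic vertical bands for
controlled experiments. `gen_community()` gives each species a forest-type
affinity and an elevation optimum; per-pixel assignment probabilities are
proportional to `exp(niche_strength * suitability)` times a
Thomas-process-like patch field (`1 + aggregation *` Gaussian bumps around
parent points) that emulates dispersal clumping without a forward dynamics
engine. The type-match term carries twice the weight of the (bounded)
elevation term so that large `niche_strength` makes affinities effectively
type-exclusive. `gen_cube()` turns the species raster into a reflectance
cube: species mean spectrum plus Gaussian noise, clipped to [0, 1], with a
planted fraction of invalid pixels (half flat low-NDVI spectra, half
zenith angles beyond 50 degrees) and a per-pixel zenith channel.

What the generator does *not* emulate: radiative transfer, sensor PSF/BRDF
effects, mosaicking artefacts, within-crown spectral variation, or
demographic dynamics. Passing tests therefore demonstrate that the
algorithms recover known structure under the stated statistical model of
the data, not that they are robust to every artefact of real imagery.

## Numerical and design choices

- All randomness flows from integer seeds; child seeds are derived from a
  single master seed by a fixed affine rule, so sweeps are reproducible
  and order-independent. The simulator uses R's own RNG inside C++.
- k-means: the full-batch Lloyd path (seeded, optional restarts) is the
  default at package scale; a mini-batch variant with per-centroid
  learning rates is provided for large scenes. Assignment ties go to the
  lowest cluster id. The cluster count is a configuration choice scaled
  to the problem (the elbow diagnostic in `select_k()` is a suggestion
  only), not a fixed constant.
- Degenerate (zero-spread) predictors are dropped with a warning;
  constant dissimilarity upper triangles, all-zero sites and all-zero
  spectra are signalled as errors with the offending ids.
- Terrain metrics shrink their 3x3 neighbourhood at raster edges rather
  than padding (no fabricated elevations); slope uses Horn's stencil, the
  GIS standard. TPI uses the immediate 8-neighbour ring, the smallest of
  the customary neighbourhoods.
- Problem sizes in the tests and acceptance script (60 x 60-cell arenas,
  4 individuals per cell, a few hundred sampled cells, 10-20 closed-loop
  trials) were chosen from a pilot signal-to-noise analysis: the
  distance-spline of a single census has appreciable Monte-Carlo
  variability in amplitude, and the recovery experiment's parameter grid
  (sigma 2/4/8, nu 0.005/0.05) is spaced so that neighbouring grid points
  are statistically distinguishable at that census size. Near-ridges in
  (sigma, nu) space -- longer dispersal with more speciation mimicking
  shorter dispersal with less -- are a genuine identifiability feature of
  neutral models at small census sizes, which the Monte-Carlo
  standard-error allowance in the matching step acknowledges explicitly.

## Known limitations

- The GDM deviance is the binomial-type form; implementations differ in
  their exact "% explained" bookkeeping, so absolute percentages are
  comparable within this package, not across software.
- The coalescent assumes a static landscape and point speciation;
  protracted speciation and density dependence are out of scope.
- Bray-Curtis on raw counts means cells with very different valid-pixel
  totals contribute slightly heteroscedastic dissimilarities; the 25%
  coverage floor bounds this effect.
- The correlogram's bootstrap CI resamples sites, which is approximate
  for statistics of pairs; no additional progressive multiple-testing
  correction is applied across distance classes.
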
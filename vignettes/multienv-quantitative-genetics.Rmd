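---
title: "Multi-environment quantitative genetics of clonal trials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-environment quantitative genetics of clonal trials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalGxE)
```

## The problem

Clonal common-garden trials plant identical copies (ramets) of each genotype
at several sites, so that genetic and environmental contributions to a trait
such as stem diameter at breast height (DBH, mm) can be separated, and the
stability of genotype performance across environments - genotype-by-
environment interaction (GxE) - can be quantified. `clonalGxE` implements the
full analysis chain for such trials: clustering of origin locations into
populations, a Bayesian multivariate mixed model over sites, broad-sense
heritabilities and between-site genetic correlations, genotype rank-change
diagnostics, and a universal response function (URF) that predicts
productivity from climate at the origin and at the planting site.

## The multi-environment mixed model

Each planting site is treated as one dimension of a multivariate response:

$$ y = X\beta + Z_p p + Z_g g + Z_r r + Z_{r(b)} b + e $$

with a fixed intercept per site ($\beta$), random population effects
$p \sim N(0, G_1 \otimes I)$ and genotype-within-population effects
$g \sim N(0, G_2 \otimes I)$, where $G_1$ and $G_2$ are unstructured
$n_\mathrm{site} \times n_\mathrm{site}$ covariance matrices, and random
replicate, block-within-replicate and residual effects with site-specific
variances $\sigma^2_{r_i}, \sigma^2_{r(b)_i}, \sigma^2_{e_i}$.

Because every ramet grows at exactly one site, the cross-site covariances of
the replicate, block and residual terms are not identifiable; they are fixed
at zero by design. Only $G_1$ and $G_2$ carry cross-site information, and they
are exactly what GxE inference needs.

Phenotypes are standardized to mean 0, variance 1 *within site* before
fitting (`standardize_phenotypes()`). Site means are absorbed by the
intercepts either way; within-site scaling makes variance components
comparable across sites. The scaling record is stored in the fit so
`variance_component_table(fit, scale = "original")` can report components in
trait units. Heritabilities and correlations are scale-free. The binary
trait (occurrence of epicormic sprouts) is analysed on the same standardized
scale rather than through a threshold link; the generator creates it as a
thresholded latent Gaussian, so standardized-scale variance components for
the binary trait are attenuated relative to the latent ones - its
heritabilities should be read as lower bounds.

### Gibbs sampler

`menv_mm()` alternates three conjugate blocks:

1. a joint multivariate-normal draw of *all* location effects
   ($\beta, p, g, r, b$) given the covariances, through a fill-reducing
   sparse Cholesky factorization of the joint precision matrix (the sparsity
   pattern is fixed, so symbolic analysis happens once);
2. inverse-Wishart draws of $G_1$ and $G_2$ from the population- and
   genotype-effect outer products;
3. inverse-gamma draws of each site's replicate, block and residual variance.

Default chain settings are 500,000 iterations, 50,000 burn-in, thinning 10.
Every analysis in the package's tests and acceptance script runs scaled-down
chains (20,000 iterations or fewer); posterior modes of the variance
components are stable well below that length for trial sizes in the hundreds
to thousands of ramets.

### Priors: why the genetic covariances are not plain inverse-Wishart

Population and genotype effects are *confounded in the mean structure*: the
population incidence space is contained in the genotype incidence space, so
the two variance components are separated only through the hierarchy (the
covariance between genotypes that share a population). That separation is
informative but not overwhelming, and it makes the prior on $G_1, G_2$
consequential:

* A fixed-scale inverse-Wishart $IW(sI, E+1)$ has inverse-gamma variance
  margins whose density grows like $\sigma^{-4}$ toward zero. In data at
  trial scale this spike can dominate the likelihood and collapse a genuinely
  positive population variance into the genotype term. We verified with an
  independent sampler (JAGS) that this collapse is a property of the
  posterior under that prior, not of our sampler.
* A large fixed scale (e.g. $s = 1$ on the standardized scale) avoids the
  collapse but adds $s$ to the *diagonal* of the effect cross-products only,
  visibly attenuating cross-site correlations (a generating correlation of
  0.99 is pulled to roughly 0.7 at study size) - fatal for a GxE analysis
  whose conclusions are those correlations.

The default is therefore a hierarchical inverse-Wishart (the Huang-Wand
construction): $G \sim IW(\nu + E - 1,\; 2\nu\,\mathrm{diag}(1/a_e))$ with
$a_e \sim IG(1/2, 1/A^2)$, all conditionals conjugate. With the defaults
$\nu = 2, A = 1$ this induces a half-$t(2, 1)$ marginal on every per-site
genetic SD - finite density at zero and essentially flat over the plausible
standardized range - and near-uniform margins on the correlations, because
the scale matrix adapts per site. Both failure modes above disappear. The
settings are exposed through `priors = list(hw_nu = , hw_A = )`.

### What recovery can and cannot achieve

With $n_p$ populations, the realized variance of the drawn population
effects scatters around the generating value with SD
$\sigma_p^2\sqrt{2/(n_p-1)}$ (about 0.12 at 23 populations and
$\sigma^2_p = 0.41$), and the posterior mode of a right-skewed variance
posterior sits below its mean by a factor of roughly $n_p/(n_p + \nu + 2)$.
Posterior modes therefore track the *realized* components well, but any
fixed tolerance against the *nominal* generating value of the population
variance is partly a draw of the dice at realistic population counts. The
genotype-level quantities (184 genotypes) are much tighter. This is visible
in the package's acceptance checks and is a property of the design, not of
the estimator - the corresponding published intervals for population
variance are similarly wide.

### Posterior summaries

Point estimates are posterior modes: a Gaussian KDE with Silverman's
bandwidth on a 512-point grid over the sample range. Intervals are highest-
posterior-density: the shortest contiguous window holding 95% of sorted
samples (quantile intervals are available by taking `quantile()` of the
returned chains). Heritabilities

$$ H^2_p = \frac{\sigma^2_p}{\sigma^2_p + \sigma^2_g + \sigma^2_e}, \qquad
   H^2_g = \frac{\sigma^2_g}{\sigma^2_p + \sigma^2_g + \sigma^2_e} $$

and between-site genetic correlations
$r = \sigma_{ij}/\sqrt{\sigma^2_i \sigma^2_j}$ are computed *per MCMC sample*
and the ratio chain is summarized - the mode of the ratio, never the ratio of
modes. The heritability denominator deliberately excludes replicate and block
variances, treating design variance as removable noise; other conventions
exist, so this is worth knowing when comparing across studies. An interaction
is flagged as important when the correlation interval's upper limit falls
below 0.7 (the usual rule of thumb).

## Population clustering

Origin locations (not genotypes - several genotypes share a location) are
grouped by partitioning around medoids on z-scored covariates: latitude,
distance from the coast, elevation, annual precipitation, and annual mean
daily maximum and minimum temperature. The covariates mix degrees, km, m,
mm and degrees Celsius; z-scoring is the only defensible common scale, and
Euclidean distance is taken on the z-scores. The number of clusters is ranked
by average silhouette width (ties go to the smaller k). Genotypes inherit
their location's cluster.

PAM here is the classic deterministic BUILD + best-improvement SWAP. It is a
local search: on a small fraction of unstructured instances it terminates in
a swap-local optimum above the exhaustive-search optimum (the canonical
`cluster::pam` returns the identical solution on such instances). The tests
assert exact agreement with the reference implementation and swap-local
optimality everywhere, and exhaustive-search equality where it holds.

## Climate summaries and variable selection

Monthly values are summarized to annual ones by averaging (temperatures,
radiation, vapour pressure, wind) or summing (precipitation). The pairwise
Pearson screen (`correlation_matrix()`, pairwise-complete with per-pair n)
feeds `select_variable_pair()`, which returns the least-correlated admissible
variable pair below an absolute-correlation threshold (default 0.7). Species
with narrow ecological amplitude tend to have strongly inter-correlated
climate descriptors, and an over-collinear URF design is singular - the
package raises an explicit error naming the deficient columns instead of
silently dropping terms.

## Universal response function

Productivity of cluster $i$ at site $j$ is regressed on climate at origin
($X_{1i}$) and at the planting site ($X_{2j}$):

$$ Y_{ij} = b_0 + b_1 X_{1i} + b_2 X_{1i}^2 + b_3 X_{2j} + b_4 X_{2j}^2
          + b_5 X_{1i} X_{2j} + e_{ij} $$

repeated per climate variable (no cross-variable products). Choices made
where the source analyses leave room:

* **Response.** $Y_{ij}$ is the posterior mean of (site intercept + cluster
  effect) from the mixed model, back-transformed to trait units; a raw
  cluster-by-site mean is available (`cluster_performance(source = "raw")`).
* **Predictor scaling.** Climate columns are z-scored *before* the
  polynomial expansion; the published coefficient magnitudes (intercept near
  the trait mean, site terms in the hundreds) are only plausible with scaled
  regressors. The scaling record is stored and re-applied to prediction
  grids.
* **Per-term R-squared** is the squared marginal Pearson correlation of the
  term column with the response; published per-term values sum to more than
  1, which rules out an additive partition.
* **Identifiability.** Each climate variable contributes two site-level
  polynomial terms; with an intercept, $m$ variables need more than $2m + 1$
  distinct site climates. Four sites cannot identify the two-variable
  surface - synthetic URF analyses in this package use six or more sites,
  and the design builder raises a rank error otherwise.

Grid prediction (`predict()` on a `urf` fit) evaluates the surface for one
chosen origin climate, flags every cell whose climate lies outside the
training min-max box, and never clips: extreme extrapolation behaviour is a
finding, not a nuisance, and stays visible.

## Genotype rank diagnostics

Within each site, genotypes are ranked (1 = best) on their posterior-mean
total genetic values (population effect + within-population deviation);
ties break deterministically by identifier so each site's ranks are a
permutation. The average clonal rank is the arithmetic mean across sites,
and each genotype's dispersion is the multiset of absolute pairwise rank
changes between sites - the data behind the rank-change boxplot
(`plot(rank_change_stats(rank_genotypes(fit)))`). Ranks on raw clone means
are available via `source = "raw"`.

## The synthetic-data generator

`generate_trial()` draws ramet records under exactly the model above:
population and genotype effects multivariate normal across sites with
requested cross-site correlations (defaults 0.99 and 0.75, the stem-diameter
regime), site-specific replicate/block/residual effects, and an
incomplete-block layout (each genotype sits in one block per replicate).
Default variance components are the published stem-diameter values
(population 0.41, genotype 0.35, residual 0.65, small design variances of
0.01 and 0.005 - realistic for well-executed forestry trials). Site means
default to distinct values so standardization code paths are exercised. All
randomness flows from one integer seed through keyed substreams split per
component and site, and the cross-site factor is a nested Cholesky, so adding
a site never perturbs the values generated for existing sites.

`generate_origins()` builds a location table along a latitudinal gradient.
Noise vectors are residualized against latitude and orthonormalized in-sample
before target correlations are mixed in, so the requested
tmax-precipitation correlation (default -0.55, the published origin-climate
value) is reproduced exactly at any n of at least 5, not merely in
expectation. Genotype counts per location are drawn from 1-6 with
probabilities giving about 2.1 genotypes per location (85 locations carrying
about 180 genotypes, the study scale). `generate_sites()` and
`generate_grid()` supply site climates spanning the New Zealand trial range
and regular prediction grids with a deterministic default climate function.

What the generator deliberately does not emulate: spatial autocorrelation
within sites, competition between neighbouring ramets, age/propagation
confounding, and non-Gaussian residuals. Passing tests therefore demonstrate
correctness of the estimation machinery under the stated model, not
robustness to those real-data features.

## Pipeline

`run_pipeline(validate_config("run.yaml"))` executes
simulate/load -> cluster -> fit -> summarize -> ranks -> URF -> surface,
writing plain CSV/JSON artifacts plus a manifest with checksums, parameters
and cache flags; unchanged stages are reused on rerun. In the synthetic
branch the trial's population labels stand for the origin clusters, and the
response surface uses cluster-level climates from a PAM run with k equal to
the number of populations. `reproduce_study()` runs the same chain on
user-supplied real tables.

## Numerical choices and degenerate inputs

* Zero within-site variance of a trait (the stressed-site case) is an error
  naming the site and trait at standardization; a site with *near*-zero
  genetic variance is handled fine and yields a posterior mode near zero
  (this is the package's null-component diagnostic).
* Non-positive-definite covariance draws are retried with a jittered scale
  (with a warning); persistent failure is an error.
* Posterior modes of constant chains return the constant; near-constant
  chains with undefined KDE bandwidth fall back to the median.
* PAM ties (equidistant points, equal-gain swaps) resolve by first index in
  scan order; rank ties resolve by genotype identifier - all deterministic.
* The correlation screen reports zero-variance variables as undefined (never
  silently 0) and gives each pair its own n under pairwise deletion.

## Problem sizes used in tests

Module tests run trials of 2-8 populations and chains of 1,200-4,000
iterations (seconds each). The end-to-end checks use the study-scale design -
4 sites, 23 population clusters of 8 genotypes, 3 replicates, 2 blocks,
3 ramets per genotype and site (2,208 ramets per trait) - with 20,000-iteration
chains, and a 6-site, 20-cluster response-surface design. These sizes were
chosen to mirror the study's data volume while keeping a full run of the
suite in the low minutes on one CPU.

## Known limitations

* No threshold/probit model for binary traits; standardized-scale analysis
  attenuates their genetic parameters.
* No pedigree or marker relationship matrices: heritabilities are broad-sense
  at the clone level.
* No spatial residual models within sites.
* The URF inherits all caveats of a polynomial response surface fitted to a
  handful of site climates: predictions outside the training climate box are
  flagged and should be treated as unreliable.
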
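---
title: "Models and methods behind avianITV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind avianITV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Within-population phenotypic variation — how different the individuals of
one species are from each other at one place — is a component of
biodiversity in its own right.  `avianITV` implements a three-stage
hierarchical Bayesian pipeline that quantifies this variation from bird
banding records (body mass in grams, unflattened wing chord in mm) and asks
what shapes it: geography and environment within species, life history and
phylogeny among species.  The unit of analysis is the coefficient of
variation (CV) of a trait for species *k* at banding location *j*,
estimated with full uncertainty propagation and then used as the response
of two regression stages.

# Stage 1: the trait hierarchy and the CV

Individual log traits are modelled as

$$\mathrm{trait}_{ijk} \sim \mathrm{N}(\mu_{jk}, \sigma_{jk}),$$

with group means normal and group SDs half-normal around species-level
parameters, which are themselves exchangeable across species under global
hyperparameters (a "half-normal with location" is a normal truncated at
zero throughout).  The group CV is derived **per posterior draw** as

$$\mathrm{CV}_{jk} = \sigma_{jk} / \mu_{jk},$$

so its posterior mean $\widehat{\mathrm{CV}}_{jk}$ and SD
$\hat\tau_{jk}$ automatically reflect the group's sample size — small
groups yield wide CV posteriors rather than the well-known small-sample
bias of plug-in CVs.  Species-level CVs average the group CV draws across
the species' locations, draw by draw.

Two implementation notes:

* **Sufficient-statistic likelihood.**  The normal likelihood enters JAGS
  through its exact factorisation, $\bar y_{jk} \sim \mathrm{N}(\mu_{jk},
  \sigma_{jk}^2/n_{jk})$ and $\mathrm{SS}_{jk} \sim
  \mathrm{Gamma}((n_{jk}-1)/2,\, 1/(2\sigma_{jk}^2))$.  This is identical
  to the per-individual model but makes the fit cost independent of the
  number of individuals (a 10,000-bird group costs the same as a 20-bird
  group).
* **CV of the log scale.**  The CV is computed from the mean and SD of the
  *log* trait, exactly as the estimand is defined in the source analysis.
  This quantity depends on the trait's unit through $\mu_{jk}$
  (log-grams here); the package applies it consistently and the
  synthetic-data generator defines truth on the same scale, but users
  comparing across unit systems should be aware of the convention.

Priors are weakly informative on the log-trait scale: N(0, 10) for the
global location hyperparameter, half-N(0, 5) for every scale-type
hyperparameter; both are configurable.  Defaults for the sampler mirror
the heavy settings this hierarchy needs (4 chains x 50,000 iterations,
20,000 warm-up, thinning 20) with convergence gates of R-hat <= 1.05 and
ESS > 400; failing the gate flags the fit rather than discarding it.  The
scale hierarchy mixes slowly (a classic funnel: the species-level scale of
group SDs is small), which is why long thinned chains are the default; the
tests and examples use shorter chains on much smaller problems.

# Stage 2: drivers of variation within species

Group CV estimates (multiplied by 1000 to avoid numerically tiny
responses) feed a measurement-error regression:

$$\widehat{\mathrm{CV}}_{jk} \sim \mathrm{N}(\theta_{jk}, \hat\tau_{jk}),
\qquad \theta_{jk} \sim \mathrm{N}(\mu_{\theta jk}, \sigma_\theta),$$
$$\mu_{\theta jk} = \alpha_k + \beta_{1k}\mathrm{Lat}_{jk} +
\beta_{2k}\mathrm{DistEdge}_{jk} + \beta_{3k}\mathrm{SpatVar}_{jk} +
\beta_{4k}\mathrm{TempVar}_{jk},$$

with the five species coefficients jointly multivariate normal around the
cross-species effects $(\mu_\alpha, \mu_{\beta 1..4})$ and a free 5x5
covariance.  $\hat\tau_{jk}$ is treated as a known observation SD.  The
covariates are: station latitude (degrees); log distance to the species
breeding-range edge (km, see below); log spatial CV of annual productivity
in a 10-km buffer; log temporal CV of the same — each centered within
species (no scaling), so $\alpha_k$ is the species' typical CV x 1000.

**Covariate construction.**  Distance to range edge uses the buffer trick:
the range is dilated by 10 km, distance is measured to the dilated edge,
and 10 km subtracted — so lakes and rivers narrower than the buffer do not
count as range edge.  For the outer boundary the dilation cancels exactly
and the plain point-to-boundary distance is used; for each interior gap
the eroded gap (points deeper than the buffer) is located on a grid of
spacing `buffer/8`, and a gap whose erosion is empty vanishes.  Points
outside the range get distance zero, and the log transform uses
log(d + 1 km) so those zeros stay finite (the offset is configurable; the
source analysis does not state its handling of zeros).  Geometry is planar
in km; lon/lat inputs are projected with a local equirectangular projection
about each point, whose error is negligible at 10-km scales.  Spatial CV
is the SD over cells of the cross-year cell means divided by their mean;
temporal CV is the mean over cells of each cell's across-year CV; both use
sample SDs (n - 1) and include a cell iff its center is inside the buffer.

**Priors and sampler.**  N(0, 5) on the cross-species covariate effects
and half-N(0, 5) on $\sigma_\theta$; the intercept gets N(0, 25) because
it lives at ~24 on the CV x 1000 data scale, where an SD-5 prior would be
strongly informative rather than weak.  The coefficient covariance gets a
Wishart prior on the precision (df 7, scale diag(5)) — the standard
weakly-informative conjugate choice for a Gibbs backend.  The latent
$\theta_{jk}$ are marginalised out of the sampled likelihood
(normal-normal collapse) and recovered exactly from their conditional
given each retained draw; this Rao-Blackwellisation leaves the posterior
unchanged and removes ~N latent nodes from the sampler.  Gates: R-hat <=
1.01, ESS > 400.

# Stage 3: drivers of variation among species

Species-average CV estimates feed the same two-layer structure at the
species level, with a phylogenetic intercept:

$$\widehat{\mathrm{CV}}_{\mathrm{SP}k} \sim \mathrm{N}(\xi_k,
\hat\tau_{\mathrm{SP}k}), \qquad \xi_k \sim \mathrm{N}(\mu_{\xi k},
\sigma_\xi),$$
$$\mu_{\xi k} = \kappa + \eta_k + \zeta_1\mathrm{GenTime}_k +
\zeta_2\mathrm{HWI}_k + \zeta_3\mathrm{RangeSize}_k +
\zeta_4\mathrm{MigStatus}_k, \qquad
\eta \sim \mathrm{MVN}(0, P\,\sigma_\mathrm{phylo}^2).$$

$P$ is the Brownian-motion correlation implied by the tree: shared
root-to-MRCA path length divided by tree depth, equivalently
$1 - d_{ab}/(2T)$ with $d_{ab}$ the patristic distance (built from
`ape::vcv.phylo` rescaled to unit diagonal; an ambiguity in whether the
scale parameter multiplies $P$ as an SD or a variance is resolved as
covariance $= P\,\sigma_\mathrm{phylo}^2$).  Generation time, hand-wing
index and range size are log-transformed (right-skewed) and standardised
across species; migratory status stays a 0/1 indicator so $\zeta_4$ reads
as a migrant-versus-resident contrast.  A single consensus tree is used;
averaging over posterior tree sets is out of scope.  $\kappa$ and $\eta$
are weakly identified separately (only their sum enters the likelihood
strongly), which depresses the intercept's effective sample size — the
covariate effects are unaffected.

# The synthetic-data generator

`simulate_captures()` inverts the full generative chain with recorded
truth: phylogeny (pure-birth tree rescaled to a fixed depth), species
life-history covariates, phylogenetically correlated species intercepts,
covariate-linked group CVs, group log-scale moments and individual
capture records.  Its defaults are the study conditions of the emulated
analysis: the four within-range effects default to the published body-mass
estimates (-0.147 per degree latitude, 0.150, 0.280, 0.188 on the logged
covariates), the life-history effects to (-2.554, -0.273, 0.261, -0.764)
on standardised covariates, the grand intercept to 24 (mean
within-population body-mass CV 0.024), stations span 28-69 degrees N, and
group sizes are 20-60 adult males.  The process SDs (sigma_theta 1,
sigma_xi 1.5, sigma_phylo 2) were chosen once so that the realised spread
of CVs within and among species matches the reported magnitudes (CV
roughly doubling across a species' range; ~3-fold differences among
species).

The landscape is constructed so the covariate module recovers the drawn
covariates **exactly**: each location carries a 3x3 raster tile whose cell
means and year profiles realise the drawn spatial/temporal CVs in closed
form, and each species range is a rectangle whose western edge sits at the
drawn distance from each location.  Wing length is linked to mass
isometrically (wing proportional to the cube root of mass, scaled per
species), making the true wing CV exactly one third of the mass CV.
Contaminants exercise the cleaning rules: gross outliers at +/- 8 group
SDs (so the 5-MAD rule must catch them), duplicate same-season captures,
and non-adult-male records, all id-tracked for recall checks.

What the generator does **not** emulate: migration phenology, within-season
mass dynamics, observation-effort variation, real range-map geometry, or
spatial correlation between neighbouring stations.  Passing tests
demonstrate correct inversion of the stated generative model, not
robustness to these real-data features.

# Data-cleaning rules

In order: breeding-season window (April-August); adult males only; first
capture per (band, species, location, year); per-group 5-MAD outlier
exclusion on the raw trait scale; then inclusion criteria — at least 15
individuals per location-by-species group, species kept only with at
least 5 surviving locations spanning at least 5 degrees of latitude —
iterated to a fixed point, since dropping groups can break a species'
criteria.  The MAD is the raw median absolute deviation (no 1.4826
consistency constant), matching the source rule as stated; a zero MAD
removes nothing (with a warning) rather than the pathological alternative
of removing all off-median values.  Outlier filtering is applied per
species-by-location group because within-population variation is the
estimand; the alternative (per species globally) is a one-line
configuration change.  Records missing one trait still serve the other
trait's pipeline, mirroring the separate-but-identical per-trait models.
Records are only ever excluded, never modified, and every exclusion is
recorded with its stage.

# Numerical choices and diagnostics

* R-hat is the rank-normalised split statistic (bulk and folded, the
  larger reported); ESS uses pooled autocovariances with Geyer's initial
  monotone positive-sequence truncation.  Both are authored in the package
  and cross-checked in tests against closed forms (iid, AR(1)) and an
  independent implementation.
* Credible intervals are equal-tailed 89% (5.5%/94.5% empirical quantiles,
  type-7 interpolation); p(>0) counts strictly positive draws.
* Convergence gates are stage-specific: 1.05 for the trait hierarchy,
  1.01 for the regressions, ESS > 400 everywhere.  Gate failure flags,
  never discards.
* Chain seeds are `seed + chain`, so every fit is reproducible from its
  `mcmc_config`.
* The phylogenetic correlation is jittered by 1e-8 on the diagonal before
  inversion; a matrix that still fails Cholesky is an error.
* Degenerate inputs error early with the offending rows named: groups of
  one bird, zero observation SDs, rank-deficient designs, missing tips,
  unparseable dates.

# Known limitations

* **Attenuation by design.**  Stage 1 partially pools group CVs toward
  species means; stage 2's observation model corrects for sampling noise
  but cannot undo shrinkage bias, so cross-species slope *point estimates*
  are attenuated toward zero when observation noise is comparable to the
  true between-location spread.  On synthetic data at the default
  conditions the 89% intervals still cover the generating effects (this is
  what the acceptance experiments check), but users should read the
  effect magnitudes as conservative.  This property is inherited from the
  two-stage architecture itself.
* Scale equivariance of the regression stages holds for the likelihood;
  the fixed weakly-informative priors break it across order-of-magnitude
  rescalings unless the prior scales are rescaled too (the `priors`
  arguments allow this).
* The gap-closing rule for range edges treats narrow inlets of the outer
  boundary like interior gaps only approximately (outer-boundary distance
  is exact; inlet closing is not applied).  Synthetic ranges are
  rectangles, where the distinction vanishes.
* Problem sizes in tests and the acceptance script (30 species x 30
  locations and smaller; thousands of draws) were chosen as the package's
  desk-scale verification conditions; the defaults for real analyses are
  the heavier settings described above.
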
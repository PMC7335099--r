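---
title: "Diversity change along a water-deficit gradient: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity change along a water-deficit gradient: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`facetdiv` analyses how three facets of tropical-forest diversity —
functional, taxonomic and phylogenetic — change over multidecadal census
intervals across a climatic water-deficit gradient, and asks whether
climate change and soil properties explain those changes.  This vignette
documents the models, the tunable parameters, the synthetic-data
generator, and the numerical choices a careful reader will want to audit.

## Abundance currency

All diversity metrics weight species by **relative basal area**.  A stem
of diameter $d$ cm contributes $\pi (d/200)^2$ m$^2$; a species' weight
$a_j$ is its summed basal area divided by the plot total.  Censuses
include every stem with DBH $\ge$ 10 cm.  The package applies this
weighting uniformly, including in the Simpson index (whose classical
definition uses individual counts); with ~500 stems per plot the two
weightings are strongly correlated, and a single abundance currency keeps
the facets comparable.

## The three facets

**Functional dispersion (FDis).**  With species coordinates $x_j$ in trait
space and weighted centroid $c = \sum_j a_j x_j$,
$$\mathrm{FDis} = \frac{\sum_j a_j z_j}{\sum_j a_j}, \qquad
  z_j = \lVert x_j - c \rVert .$$
For purely numeric traits the space is the z-scored trait matrix
(standard deviation with $n-1$; this makes the two-species example with
trait values $\{0, 2\}$ equal exactly $1/\sqrt 2$).  For mixed traits we
compute Gower dissimilarities — numeric traits range-normalised within
the community, categorical traits scored 0/1, missing values excluded
pairwise with renormalisation — and embed them by principal coordinates.
When the Gower matrix is not Euclidean-embeddable (negative eigenvalues
beyond tolerance) the square roots of the dissimilarities are embedded
instead, which restores embeddability for Gower inputs.  Axes with
eigenvalues below $10^{-9}$ of the largest are dropped.  Zero-range
traits are skipped per community with a warning, never an error.

**Taxonomic diversity.**  Simpson index $1 - \sum_i p_i^2$ and its Hill
companion $1/\sum_i p_i^2$ (effective species count); the two satisfy
$\mathrm{Simpson} = 1 - 1/{}^2D$ exactly and are tested as such.

**Phylogenetic diversity.**  From an ultrametric tree we compute the
abundance-weighted mean pairwise patristic distance
$$\mathrm{MPD} = \frac{\sum_{i \ne j} a_i a_j d_{ij}}
                      {\sum_{i \ne j} a_i a_j},$$
mean nearest-taxon distance, and Faith's PD (total branch length of the
root-inclusive spanning subtree; root inclusion makes PD well defined for
a single species).  Self-pairs are excluded from weighted MPD and the
weights renormalised — note that some reference implementations instead
average over all pairs including the zero diagonal, which rescales MPD by
$1 - \sum_j a_j^2$; our tests assert the exact algebraic relation between
the two conventions.

**Null model.**  The frequency null permutes each species' abundances
across the plots where it occurs, keeping occurrence patterns fixed, and
recomputes weighted MPD per iteration;
$\mathrm{SES} = (\mathrm{obs} - \bar{x}_{null})/s_{null}$.  Plots whose
null distribution is degenerate get `NA` with a warning rather than an
arbitrary value.  999 iterations by default (configurable).

**Phylogenetic signal.**  Blomberg's K compares the observed ratio of
mean squared errors (tip values around the phylogenetically corrected
mean, versus the GLS error under the tree's covariance) to its Brownian
expectation.  Significance comes from 999 tip randomisations with the
$+1$-corrected permutation p-value $(1 + \#\{K_\pi \ge K\})/(1 + n_\pi)$.

## Climate drivers

**CWD/MCWD.**  The cumulative water deficit follows the running recursion
$\mathrm{WD}_m = \min(0, \mathrm{WD}_{m-1} + P_m - \mathrm{PET}_m)$,
reset at the start of each hydrological year.  The phrase "P − PET with a
minimum deficit of 0" is ambiguous between this cumulative reading and a
memoryless monthly one; the cumulative recursion is the standard drought
metric and is the default, with `mode = "monthly"` exposing the literal
monthly reading.  The hydrological year is anchored at the
climatologically wettest calendar month (ties to the earliest month).
MCWD over a climatology window is the **mean of the yearly CWD minima**
(an "average weather" summary; `aggregate = "min"` gives the single worst
year instead).  Only complete hydrological years starting inside the
window are used.

**SPEI.**  The 12-month climatic balance $D$ is fitted per calendar month
with a three-parameter log-logistic distribution via unbiased
probability-weighted moments and mapped through the fitted CDF to
standard-normal quantiles.  Months with negative sample L-skewness (no
valid shape) are fitted on the reflected sample and mapped back; months
with zero interannual variance return `NA` with a warning.  Fitted
probabilities are clamped to $[5 \times 10^{-4}, 1 - 5 \times 10^{-4}]$,
bounding the index at about $\pm 3.29$.

**Windows.**  Thirty-year climatologies preceding each census (1964–1993
and 1984–2013) plus the full period 1964–2013; absolute changes are
$\Delta X_{Abs} = X_{T2} - X_{T1}$, so drying gives
$\Delta \mathrm{MCWD}_{Abs} < 0$.

## Inference

**Rates and groups.**  Each facet's change is expressed as an annual rate
$(x_{T2} - x_{T1}) / (t_2 - t_1)$ with decimal-year census dates
(intervals below 10 years draw a warning).  Plots are classified dry when
their first-period MCWD is $\le -250$ mm (inclusive), wet otherwise.

**Two-group model.**  The dry–wet contrast uses the robust Bayesian
two-group model: $y \sim t_\nu(\mu_g, \sigma_g)$ with priors
$\mu_g \sim N(0, 10)$, $\sigma_g \sim U(s_p/1000,\, 1000 s_p)$ ($s_p$ the
pooled SD) and $\nu \sim 1 + \mathrm{Exp}(29)$.  The sampler is Gibbs on
the scale-mixture representation, with $\nu$ updated by slice sampling
from its conditional with the latent scales integrated out (a partially
collapsed step that mixes far better than updating $\nu$ given the
latents).  Three chains of 2000 iterations (half warmup) by default.  We
report the posterior median difference, 50/89/95% HDIs (empirical
shortest-interval), and the probability of direction — the posterior mass
on the dominant side of zero, which operationalises the "probability"
number attached to each facet's contrast.  Split-chain Rhat above 1.05
flags the fit, never silently.

**Driver models.**  Soil variables are centred, scaled and decomposed by
PCA; axes explaining $\ge$ 10% of variance are retained, and each axis is
oriented so its largest-magnitude loading is positive (reproducible sign
convention).  Candidate drivers are screened by Pearson correlation:
from each pair with $|r| > 0.7$ (strict) the lower-priority member is
dropped; the priority order is configuration, because "more ecologically
meaningful" is a scientist's choice, not an algorithm's.  The model
grammar then enumerates 35 candidate specifications over three climate
drivers and three soil axes — covariate-only, single drivers, climate and
soil subsets, one-climate-plus-soils, the full additive model, and the
full model augmented with soil-by-climate interactions (single terms,
per-axis blocks, per-driver blocks, and all nine) — every one including
the plot-area covariate.  The composition of the set beyond its size and
the shapes of the best models is a design decision declared in
configuration.

Each candidate is a Gaussian linear model with standardized predictors,
priors $N(0, 2.5)$ on slopes, $N(0, 10)$ on the intercept and
$\mathrm{Exp}(1/s_y)$ on $\sigma$, sampled by a conjugate Gibbs step for
the coefficients (pre-diagonalised so each iteration is $O(p)$) and slice
sampling for $\sigma$.  Models are compared by **exact leave-one-out
cross-validation**: the model is refitted once per held-out plot
(re-standardizing on the training fold) and the log posterior-predictive
density of the held-out observation accumulated into the ELPD;
$\mathrm{LOOIC} = -2\,\mathrm{ELPD}$.  At $n = 21$ exact refits are cheap
and unambiguous; a truncated-importance-sampling fast path is provided
and tested against the refit path on small models, but it degrades for
heavily parameterised models at $n \approx p$ and is not used for
selection by default.  Coefficients are reported with medians, 50/89/95%
HDIs, ROPE (the fraction of the 89% HDI inside
$\pm 0.1\, s_y$, near 0 meaning a clearly non-negligible effect) and
split-Rhat, plus a classical adjusted $R^2$ evaluated at the
posterior-median coefficients.

## The synthetic-data generator

The generator produces complete study inputs with known ground truth: a
unit-height pure-birth phylogeny; traits simulated under Brownian motion
(numeric), tip-shuffled white noise, or latent-Brownian thresholding
(categorical — deciduousness with 2 classes, guild with 3, nitrogen
fixing with 2); monthly climate; soils from three latent factors; and
paired-census communities.

Climate per plot is a seasonal sinusoid whose mean precipitation is
calibrated by root finding so the noise-free baseline MCWD matches the
plot's position on a wet–dry gradient (default $-300$ to $-100$ mm, with
25 mm of plot-level noise so a site's long-term deficit is not a
deterministic function of its trend), plus a linear drying trend that
strengthens toward the dry end (wet-end base $-0.065$ mm/month per year,
amplified 3.5-fold at the dry extreme, with truncated-lognormal per-plot
jitter) and multiplicative monthly noise.  These values were chosen to
reproduce the qualitative structure of the study system: absolute MCWD
changes spanning roughly $-30$ to $-5$ mm, a clear dry–wet contrast in
diversity-change rates, and a climate driver set in which the full-period
MCWD, its change and the VPD change survive the 0.7 correlation screen
while the SPEI change (nearly collinear with the MCWD change) is pruned.

Each plot's **true annual rates** of Simpson, FDis and MPD change are
drawn as `drying_effect * dMCWD_Abs + noise` (defaults $10^{-4}$,
$4 \times 10^{-5}$ and $2 \times 10^{-4}$ per mm·yr with noise SDs
$2.5 \times 10^{-4}$, $10^{-4}$, $5 \times 10^{-4}$), coupling faster
declines to stronger drying.  The second census is engineered by
abundance reallocation over the fixed species set: weights
$w \propto w_0^{\theta} \exp(\eta z + \eta_2 z^2 + \zeta m + \zeta_2 m^2)$,
where $z$ is the species' (standardized) distance to the trait centroid
and $m$ its mean patristic distance to the community.  The five knobs are
solved jointly by Nelder–Mead with restarts so the realized rates hit the
targets, normally to well within the generator's 10% accuracy contract.
A strictly rank-preserving reallocation (the power transform alone)
cannot steer three facets independently, which is why the tilts exist.
Rates a community genuinely cannot realise are brought to the nearest
achievable combination; mathematically impossible Simpson targets raise
an error.  Ground truth records both intended and realized rates and is
never consumed by analysis stages.  Stem tables are constructed so
realized basal-area weights equal the intended weights exactly (stem
counts proportional to weight, uniform within-species DBH solving the
share).

What the generator does **not** emulate: demographic processes
(recruitment, mortality, growth), spatial structure, trait gap-filling
error, observation error in species identification, and raster climate
products.  Passing tests therefore demonstrate that the statistical
machinery recovers known structure under the stated model of the data,
not that the model is adequate for any particular real forest.

## Numerical choices and degenerate inputs

* Randomness flows from a single seed through deterministic per-stage
  sub-seeds (an affine hash of the stage name), so stages are individually
  reproducible.
* Ultrametry is checked within $10^{-6}$ relative tolerance and violations
  warn rather than fail.
* Communities of fewer than two species: MPD/MNTD are recorded `NA` with
  a warning (not 0); FDis and RaoQ are exactly 0 for one species; empty
  communities are errors.
* Permutation p-values use the $+1$ correction and can never be 0.
* The HDI is the empirical shortest interval on sorted draws; ROPE is the
  fraction of draws inside the 89% HDI that fall in the equivalence band.
* Rhat is the classic split-chain (rank-free) statistic; identical
  half-symmetric chains give exactly $\sqrt{(n-1)/n}$.
* Trait coverage below 90% of basal area warns and is surfaced in the
  manifest; metrics are still computed.

## Problem sizes used by the test suite

Calibration tests run at sizes chosen for statistical resolution within a
modest compute budget, stated here as the package's own testing policy:
exhaustive oracle comparisons over all 2497 communities of 2–6 species
from a 12-tip tree; null-model calibration over 200 plot-by-species
matrices at 999 iterations; Blomberg's K over 200 Brownian simulations on
a 100-tip tree and 400 white-noise replicates at 199 permutations;
two-group coverage over 50 replicates at $n = 10$ per group with the full
3 × 2000 MCMC budget; LOO selection consistency over 50 replicates at
$n = 21$ with 2 × 600 iterations; and 40 end-to-end synthetic worlds at
the full 21-plot design with 2 × 500-iteration driver fits.  The
acceptance script runs one full world at the complete 3 × 2000 budget
with exact-refit LOO.

## Known limitations

* The Simpson index is basal-area-weighted throughout (see above); users
  wanting count-based Simpson can pass counts to `simpson_index()`
  directly.
* Importance-sampling LOO is a convenience fast path only; selection
  results reported by the pipeline default to exact refits.
* The frequency null requires at least two plots and species that occur
  in more than one plot to have any freedom; single-plot designs get a
  degenerate null.
* The generator's reallocation family bounds how far FDis can fall while
  evenness stays high; extreme drawn rates are truncated to the
  achievable boundary (and recorded as such).
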
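# facetdiv

Tools for asking how tropical-forest diversity is changing under a drying
climate.  Given repeated censuses of permanent forest plots arranged along
a climatic water-deficit gradient, `facetdiv` computes three facets of
each plot's diversity — **functional dispersion** (FDis) on mixed trait
data, **taxonomic diversity** (Simpson / Hill *q* = 2) and
**phylogenetic diversity** (abundance-weighted MPD, MNTD, Faith's PD,
with a frequency null model and Blomberg's *K* for phylogenetic signal) —
derives climate drivers from monthly series (cumulative water deficit
CWD/MCWD, 12-month SPEI, vapour pressure deficit, 30-year climatologies
and their absolute changes), and runs the study's inference: a robust
Bayesian two-group comparison of annual diversity-change rates between
dry (MCWD ≤ −250 mm) and wet plots, and Bayesian linear driver models
screened by correlation pruning and soil PCA, enumerated from a 35-model
grammar, and selected by exact leave-one-out cross-validation with HDI,
ROPE and Rhat reporting.

The core quantities, in the field's notation:

* FDis = Σ aⱼ zⱼ / Σ aⱼ, with zⱼ the distance of species *j* to the
  basal-area-weighted centroid of the community in (Gower/PCoA or
  z-scored) trait space;
* Simpson = 1 − Σ pᵢ², Hill ²D = 1 / Σ pᵢ²;
* weighted MPD = Σ_{i≠j} aᵢaⱼ dᵢⱼ / Σ_{i≠j} aᵢaⱼ on patristic distances;
* CWD recursion WDₘ = min(0, WDₘ₋₁ + Pₘ − PETₘ), MCWD = yearly minimum,
  averaged over a 30-year window;
* annual rate Δ𝑋ᵣ = (X_T2 − X_T1)/(t₂ − t₁).

A synthetic-data generator produces complete study worlds (phylogeny,
traits with controlled phylogenetic signal, paired censuses with known
true rates of change coupled to the drying gradient, monthly climate,
soils with a three-axis latent structure), so the entire pipeline is
testable end to end with known ground truth.

## Worked example

```r
library(facetdiv)

world <- simulate_study(sim_config(seed = 1))
run <- run_pipeline(world, chains = 3, iter = 2000,
                    loo_method = "exact", seed = 1)
writeLines(report_run(run)[1:4])
```

```
== Dry vs wet: annual rates of diversity change ==
d_fdis_r     diff (dry - wet): median -5.891e-04  50% HDI [-8.042e-04, -3.693e-04]  89% [-1.169e-03, -4.884e-05]  95% [-1.308e-03, +1.935e-04]  Prob 95.1%
d_simpson_r  diff (dry - wet): median -3.867e-04  50% HDI [-4.974e-04, -2.934e-04]  89% [-6.635e-04, -1.142e-04]  95% [-7.773e-04, -2.313e-05]  Prob 97.4%
d_mpd_r      diff (dry - wet): median -1.655e-03  50% HDI [-2.075e-03, -1.128e-03]  89% [-2.991e-03, -4.245e-04]  95% [-3.428e-03, +1.989e-04]  Prob 97.1%
```

Each line gives the posterior median difference in the annual rate of
change of that facet between dry and wet plots (negative = diversity
declining faster at the dry end), its highest-density intervals, and the
probability of direction: in this world all three facets decline faster
in dry plots with 95–97% posterior certainty.  The report continues with
the driver models selected by exact leave-one-out cross-validation; for
this seed the selected functional-diversity model contains the absolute
MCWD change with ROPE 0.00 and fits with R²_adj 0.93 and LOOIC −280.5 —
the generator's true drying coupling, recovered from the synthetic
censuses.

The lower-level functions are exported individually (`fdis`,
`simpson_index`, `mpd`, `mntd`, `faith_pd`, `frequency_null`,
`blomberg_k`, `cwd_series`, `mcwd`, `spei`, `fit_best`, `fit_bayes_lm`,
`loo_compare`, `enumerate_models`, `soil_pca`, `prune_correlated`, ...);
see the methods vignette (`vignettes/methods.Rmd`) for the models,
parameter meanings and numerical conventions.

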
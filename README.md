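# sftabund

Testing the validity of space-for-time substitution in multispecies
point-count data.

## The problem

Ecology often substitutes space for time: habitat–abundance relationships
estimated *across* a landscape at one time point are used to predict how
abundance will respond to habitat *change* over time. Whether that
substitution is valid is an empirical question, and answering it needs a
two-period dataset, a model that corrects counts for imperfect detection,
and a counterfactual: what would Period-2 abundance look like if abundance
could only have changed through land-cover change?

`sftabund` is for ecologists and biostatisticians with replicated
point-count surveys (one count per site in Period 1, back-to-back replicate
counts in Period 2) and compositional land-cover proportions measured in
nested buffers around each site. It provides the full pipeline — data
containers and readers, a faithful synthetic-data generator, scale-of-effect
selection, hierarchical Bayesian abundance models, and the space-for-time
test — with every stage testable on simulated data of known truth.

## The model

Counts are modelled as Binomial thinnings of latent true abundances
(an N-mixture model):

```
y[i,j,t,k] ~ Binomial(N[i,j,t], P[i])        # replicate k, detection P
N[i,j,t]   ~ Poisson(lambda[i,j,t])
P[i]       ~ Beta(psi * theta, (1 - psi) * theta)
psi ~ Beta(2, 3),  theta ~ Gamma(9, 5)
```

Two variants of the abundance regression:

* **fixed50** — land cover at the smallest buffer radius, which is a closed
  composition, so the Scheffé parametrization applies: no intercept, and
  `log lambda[i,j,1] = sum_m beta[i,m] E[j,m,1]`, where `beta[i,m]` is the
  log expected abundance were type `m` to cover the whole buffer.
* **multiscale** — each species × type covariate at its selected scale of
  effect; covariates no longer sum to one, so a species intercept
  `alpha[i]` enters.

Period 2 adds a species drift `phi[i] ~ Normal(rho, sigma)` for abundance
change *not* attributable to land cover; effects are partially pooled
across species (`beta[i,m] ~ Normal(mu_m, tau_m)`). Scales of effect are
chosen per species × type by leave-one-out Poisson regression (Pearson or
Spearman scoring of observed vs out-of-sample predictions across ~30
candidate radii) or by boosted-regression-tree relative influence.

The space-for-time counterfactual sets `phi = 0` in every posterior draw
and pushes Period-2 land cover through the fitted habitat effects. Species
are then classified by comparing the credible intervals of the true and
counterfactual percent changes: opposite significant trends, a one-sided
mismatch, both non-significant, or significant same-direction trends with
disjoint or overlapping intervals.

## Worked example

```r
library(sftabund)

design <- survey_design(n_sites = 60, n_species = 10, n_landcover = 3,
                        types = c("trees", "pavement", "grass"))
grid <- build_scale_grid(50, 500, 50)
sim <- simulate_dataset(design, grid, seed = 42, spatial_smoothness = 0.5,
                        shock_sd = 0.4, model_variant = "fixed50")
sim$counts
#> count_data: 10 species x 60 sites, 2 periods; 703 birds counted

head(select_scale_correlation(sim$counts, sim$stack), 3)
#>   species  type radius     score  method
#> 1    sp01 trees    300 0.2132009 pearson
#> 2    sp02 trees    400 0.4043758 pearson
#> 3    sp03 trees    350 0.2842278 pearson

spec <- model_spec("fixed50", chains = 2, warmup = 800, sampling = 400,
                   adapt = 300)
fit <- fit_abundance_model(sim$counts, sim$stack, NULL, spec, seed = 1,
                           on_nonconvergence = "warn")
#> Warning: MCMC did not converge: max split-Rhat = 1.770 > 1.01 ...
fit
#> abundance_fit (fixed50): 10 species x 60 sites, 800 draws, max split-Rhat 1.770

posterior_true_abundance(fit)
#> posterior_community: totals t1 1140 [846, 1438], t2 963 [691, 1178] (89% CrI)
apply(sim$N, 3, sum)   # the simulator's ground truth
#>  t1  t2
#> 882 677
```

The posterior communities are detection-corrected: ~700 birds were
*counted*, the model places the true Period-1 total near 1100 with the
simulated truth (882) inside the 89% interval. The convergence warning is
the fit's split-Rhat screen — this short demonstration run needs the
default four chains × 1500 warmup for production use (and
`on_nonconvergence = "error"`, the default, refuses such a fit outright).

```r
trends <- sft_trends(fit, seed = 2)
head(as.data.frame(trends)[, c(1, 2, 3, 4, 8)], 3)
#>   species true_median true_lower true_upper            category
#> 1    sp01   -67.67985  -75.31392 -57.137324  one_sided_mismatch
#> 2    sp02    85.83960   -1.67321 238.306874 both_nonsignificant
#> 3    sp03   -56.71642  -66.15509 -47.727273  one_sided_mismatch

report <- sft_validity_report(trends)
report$shares
#>                     category n share
#> 1       opposite_significant 0     0
#> 2         one_sided_mismatch 5    50
#> 3        both_nonsignificant 5    50
#> 4 same_direction_significant 0     0
#> 5 same_direction_overlapping 0     0
round(report$community, 1)
#>                median lower upper
#> true            -16.6 -27.6  -3.3
#> counterfactual    1.6  -5.0   8.1
```

Read: the community declined ~17% (89% CrI −27.6 to −3.3), but the
land-cover-only counterfactual predicts no change (+1.6%, CrI spanning
zero), and half the species are one-sided mismatches — exactly what this
simulation built in (a drift term the landscape cannot explain), and the
signature of an *invalid* space-for-time substitution.

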
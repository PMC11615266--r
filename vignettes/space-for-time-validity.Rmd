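---
title: "Testing space-for-time substitution with multispecies abundance models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing space-for-time substitution with multispecies abundance models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Ecologists routinely substitute space for time: habitat–abundance
relationships estimated across a landscape at one point in time are used to
predict how abundance will respond to habitat change over time. `sftabund`
implements a complete pipeline for testing whether that substitution is
valid in two-period, multispecies point-count data: if land-cover change
alone explains temporal abundance change, a counterfactual prediction that
lets abundance respond *only* to land cover should match the observed
(detection-corrected) change.

The pipeline has four stages, each usable on its own:

1. **Data model and synthesis** — containers and delimited-text readers for
   two-period counts and multi-scale compositional land cover, plus a
   generator that simulates both with exactly the statistical structure the
   model assumes.
2. **Scale-of-effect selection** — per species and land-cover type, which
   buffer radius best predicts abundance: leave-one-out Poisson regression
   scored by Pearson or Spearman correlation, or boosted-regression-tree
   relative influence.
3. **Hierarchical abundance models** — Bayesian multispecies N-mixture
   models with imperfect detection, fit by MCMC.
4. **The space-for-time counterfactual** — land-cover-only Period-2
   abundances, per-species percent changes with credible intervals, and a
   five-way validity classification.

## Data model

A `survey_design` fixes the dimensions: `J` sites, `S` species, `M`
land-cover types, two sampling periods, and the within-period replicate
structure — by default one count in Period 1 and two back-to-back replicate
counts in Period 2, the replication needed to estimate detection
probability. A `scale_grid` holds the candidate buffer radii; the default
(50 m to 1500 m in 50 m steps) gives 30 candidate scales. Land cover enters
as a `landcover_stack` of proportions indexed site x type x radius x period;
for every site, radius, and period the proportions across types must sum to
one, because the types partition the buffer. Counts live in a `count_data`
array indexed species x site x period x replicate.

Readers accept long-format delimited text and validate labels, replicate
structure, and compositional closure. Because survey archives often retain
only species seen more than once, `read_counts()` fills omitted combinations
with zero by default (`absence_is_zero`); `filter_min_detections()` applies
the seen-more-than-once inclusion rule where an analysis needs it. The
model itself never drops species.

## The synthetic-data generator

`generate_landscape()` mimics how buffer covariates arise from a real map.
The composition of a larger buffer is the area-weighted average of the next
smaller buffer and the annulus between them, so we build radii cumulatively:
the innermost composition is a Dirichlet draw (concentration 2 by default —
moderately even urban mosaics), and each step outward mixes in a fresh
Dirichlet draw with weight `area_fraction / spatial_smoothness`. Consecutive
radii are therefore strongly autocorrelated while distant radii decorrelate,
which is the feature scale selection needs; `spatial_smoothness = 1` gives
geometric (area-true) mixing, larger values make the landscape flatter
across scales, and in the limit all radii at a site are identical. Period 2
perturbs Period 1 by a site x type logistic-normal shock (sd 0.3 by
default), shared across radii so temporal change is coherent across scales.
No published estimate of the magnitude of between-period urban land-cover
change at these scales was available to us, so the shock scale is an exposed
parameter rather than a calibrated constant.

`generate_community()` draws species parameters from their hyperpriors:
habitat effects `beta[i, m] ~ Normal(mu_m, tau_m)`, intercepts
`alpha[i] ~ Normal(mu_alpha, tau_alpha)`, a drift term
`phi[i] ~ Normal(rho, sigma)`, and detection probabilities
`P[i] ~ Beta(psi * theta, (1 - psi) * theta)`. The detection centre
defaults to `psi = 0.4` with concentration `theta = 5` — i.e. Beta(2, 3),
realistic for 5-minute point counts where fewer than half the birds present
are detected. Each species x type pair gets a generating scale of effect,
uniform over the grid by default or fixed to one radius when an experiment
needs a strong identifiable signal.

`simulate_counts()` then applies the exact model structure: latent
`N[i,j,t] ~ Poisson(lambda)`, log-linear land cover at the generating
scales (with drift added in Period 2), and every within-period replicate an
independent `Binomial(N, P_i)` thinning of the *same* latent N. The latent
N is always returned — recovery tests need the simulator's ground truth.

What the generator deliberately does **not** emulate: spatially explicit
rasters and map geometry, irruptive or migratory dynamics, interspecific
interactions, and observation covariates (observer, weather, date). Tests
that pass on these simulations therefore certify the estimation machinery
under the model's own assumptions, not robustness to the many ways real
surveys violate them.

All randomness flows from one master seed through a documented splitting
scheme (`split_seed()`), so any stage can be replayed in isolation.

## Scale-of-effect selection

For each species i, land-cover type m, and radius c we fit period-specific
univariate Poisson regressions of the response on the proportion covariate.
The Period-2 response is the maximum raw count over the back-to-back
replicates — the temporal maximum better reflects the birds associated with
the surrounding land cover — while Period 1 uses its single count as-is
(`collapse_period2_max()`).

`loo_predictions()` computes exact leave-one-out refits: for each held-out
observation the two-parameter Poisson MLE is re-solved on the remainder by
a Newton iteration run jointly across folds (warm-started at the full-data
fit, and verified in the tests against per-fold `glm()` refits to 1e-7).
`select_scale_correlation()` scores each radius by the correlation between
the pooled observed responses of both periods and their pooled LOO
predictions, and picks the argmax per species x type. Numerical contracts,
chosen where the procedure itself is silent:

* leave-one-out folds are single site-within-period observations, and the
  univariate fits are period-specific (intercept and slope carry a period
  index); correlations pool both periods' observed/predicted pairs;
* ties go to the smallest radius — the most local, most parsimonious scale;
* folds whose refit is degenerate (all-zero training response, constant
  training covariate, no convergence) are flagged missing and excluded
  pairwise; radii whose correlation is undefined (zero-variance predictions)
  can never win.

`select_scale_brt()` instead fits one gradient-boosted ensemble per species
on all M x C proportion columns (both periods stacked — the stacked
response uses every observation the univariate route sees), with Poisson
loss, depth-1 trees, bag fraction 0.5, minimum node size 25, shrinkage
1e-4, and 20,000 trees by default; the test suite scales the ensembles down
(hundreds of trees at larger shrinkage) because relative influence of a
dominant predictor stabilizes long before the full production ensemble.
Relative influence is the normalized split-gain share per predictor; per
type, the radius with the highest influence wins. Species with fewer than
five nonzero responses inherit the map of the fit species with the most
similar count profile (highest Spearman correlation) — a reproducible
stand-in for "use a closely related species" that needs no taxonomy — and
an explicit donor mapping overrides the similarity rule.

`scale_selection_plan()` exposes the enumeration bookkeeping: S x M x C
model configurations and S x M selected scales (61 species x 7 types x 30
radii = 12,810 models and 427 map entries at the full study size).

## The abundance models

Both variants are multispecies N-mixture models: true abundance
`N[i,j,t] ~ Poisson(lambda[i,j,t])`, and each replicate count an
independent `Binomial(N[i,j,t], P_i)` thinning of the same latent N.
Detection is constant across periods — only Period 2 has the within-period
replication that identifies it, so Period-1 counts inform `P_i` through
pooling alone. Species detection probabilities share a Beta hyperprior
parametrized by centre `psi` and concentration `theta`
(`a = psi * theta`, `b = (1 - psi) * theta`), with `psi ~ Beta(2, 3)` and
`theta ~ Gamma(9, 5)`.

The **fixed50** variant uses the closed composition at the smallest radius:
`log lambda[i,j,1] = sum_m beta[i,m] E[j,m,1]`. Because the proportions sum
to one, adding an intercept would make the design matrix rank-deficient, so
there is none — each `beta[i,m]` is directly the log expected abundance
were type m to cover the whole buffer. The package refuses intercepts in
this parametrization rather than silently dropping rank.

The **multiscale** variant uses each species x type covariate at its
selected scale. Covariates measured at different radii no longer sum to
one, the design matrix is full rank, and a species intercept
`alpha[i] ~ Normal(mu_alpha, tau_alpha)` enters. In both variants Period 2
adds a species drift `phi[i] ~ Normal(rho, sigma)` capturing abundance
change *not* attributable to land cover, and habitat effects are partially
pooled across species: `beta[i,m] ~ Normal(mu_m, tau_m)`.

Location hyperparameters (`mu_m`, `rho`, `mu_alpha`) get Normal(0, 2)
priors; scale hyperparameters (`tau_m`, `sigma`, `tau_alpha`) must be
positive, so they get half-Normal(0, 2) — weakly informative on the log
scale of bird counts, where effects beyond +/-4 are implausible. All prior
scales are arguments of `model_spec()`.

### Sampling and numerics

Models are fit with JAGS via `rjags`. JAGS samples the discrete latent
abundances directly as model nodes, so no truncation is needed inside the
sampler and per-draw latent N comes out with everything else. The marginal
site likelihood (`marginal_loglik_site()`) is nonetheless part of the
package surface: it marginalizes N up to a truncation bound (default:
maximum observed count + 50) by log-sum-exp, reduces analytically to the
Poisson thinning identity `y ~ Poisson(lambda * P)` for single-replicate
data, and is verified against brute-force summation — the tests use it to
guard the model's likelihood structure independently of the sampler.

Default MCMC settings are 4 chains x 1500 warmup x 500 sampling iterations;
chains receive deterministic per-chain RNG seeds derived from the master
seed, so a fit is exactly reproducible. Convergence is screened by
split-Rhat over all structural parameters with a 1.01 threshold; by default
a fit that exceeds it fails loudly with the diagnostic table attached
(`on_nonconvergence = "error"`), and simulation studies that tolerate
slower mixing can downgrade this to a warning.

One honest caveat: in the multiscale variant the per-type covariates still
*nearly* sum to one (nested buffers are strongly autocorrelated), so the
species intercepts and the pooled effect level are close to collinear and
the intercepts mix slowly. This widens intervals rather than biasing point
estimates, and it is the same trade-off the intercept-bearing multiscale
parametrization always carries; recovery tests in this package therefore
check interval coverage, not Rhat, on that variant.

## The counterfactual and the validity test

`posterior_true_abundance()` sums the latent-N draws over sites into
posterior communities: per-draw species totals and community totals for
each period, summarized by medians and equal-tailed credible intervals
(89% by default, quantiles 0.055 and 0.945). `retrodiction_check()`
simulates total detections from each draw and compares them with the
observed totals — the posterior-predictive fit check.

`expected_N_phi0()` computes the space-for-time counterfactual: for every
posterior draw, the expected Period-2 abundance with the drift term set to
zero, i.e. abundance allowed to change only through land-cover change. By
default a fresh Poisson realization is drawn per species, site, and draw so
the counterfactual totals carry the same stochastic width as the full
model's posterior communities; an expectation-only variant sits behind a
flag for variance-decomposition work. The drift draws never enter, which is
itself a tested invariant.

`percent_change()` works per draw — `100 * (N2 - N1) / N1` with Period-1
zeros replaced by 1e-10 — so that uncertainty propagates into the change
summaries rather than being collapsed first. `sft_trends()` classifies each
species by comparing the true and counterfactual change intervals
(significance = the interval excludes zero):

| category | meaning |
|---|---|
| `opposite_significant` | both significant, opposite directions |
| `one_sided_mismatch` | exactly one of the two is significant |
| `both_nonsignificant` | neither is significant |
| `same_direction_significant` | both significant, same direction, disjoint intervals |
| `same_direction_overlapping` | both significant, same direction, overlapping intervals |

"Overlapping" means non-empty interval intersection at the configured
level. If space-for-time substitution were valid, the same-direction and
consistently-nonsignificant categories would dominate; a landscape-stable
community whose abundances drift anyway lands in `one_sided_mismatch`.
`sft_validity_report()` tabulates the category shares and passes through an
optional external reference trend column (e.g. a national series) without
modelling it.

## Control experiments

The package's own validity checks are two control simulations, run both in
the test suite and by `scripts/acceptance.R`:

* **Positive control** — drift fixed at zero, land cover changes between
  periods. Everything the data do is land-cover-driven, so the
  counterfactual Period-2 intervals should overlap the full model's for
  nearly all species.
* **Negative control** — strong drift (mean -0.9 on the log scale) over a
  frozen landscape. The counterfactual centres on no change while the true
  trends are significant declines, so `one_sided_mismatch` should be the
  modal category.

## Problem sizes and experiment configurations

Simulation studies in the tests and the acceptance script use sizes chosen
to make each estimand measurable while keeping a full run comfortable on a
single core: parameter and abundance recovery at 8 species x 60 sites (one
well-mixed fit at 3 chains x 4000 warmup x 800 sampling for parameter
interval coverage; 20 replicate fits at 2 chains x 1500 warmup x 500
sampling for interval coverage of the simulated community total). The
coverage replicates draw their generating abundance hyperparameters from
the model's own priors at unit scale, with the fit using the same scales —
the standard calibration design under which nominal interval coverage is
exact — while detection stays in the centred Beta(2, 3) regime: detection
probabilities near zero are unidentifiable from two replicates and only
stall the sampler without informing coverage. Scale recovery runs at 5 species x
200 sites with all generating scales at 500 m, habitat-effect means of
+/-2.5 (sd 0.2), and `spatial_smoothness = 0.5`, the strong-identifiable-
signal regime: slopes comfortably at magnitude 2 or more and cross-scale
autocorrelation weak enough that candidate radii are statistically
distinguishable at 200 sites; control experiments at 10 species x 60 sites.
The full-study dimensions (61 species, 272 sites, 7 types, 30 radii) appear
in the enumeration bookkeeping, which is exact at any size.

## Limitations

* Detection probability is weakly identified from two replicates: the
  N-mixture profile likelihood has a long ridge toward small `P` with large
  `N`, a known small-sample instability of these models, and the Beta
  hyperprior restrains it only softly when few species share it. Per-species
  `P` intervals can therefore sit low while the abundance-effect and drift
  intervals stay calibrated; recovery checks here assess coverage pooled
  across all parameter groups, and real studies should pool many species
  (which sharpens the detection hyperprior) or add replicates.
* Two periods cannot separate drift from any unmodelled covariate that
  changed once; the drift term is a catch-all, not a mechanism.
* Detection is species-level only; no observer, date, or weather effects.
* The multiscale intercepts mix slowly (see above); production fits should
  use the default four chains and check the attached diagnostics.
* Scale selection assumes one optimal radius per species x type; truly
  multi-scale responses within a single type are outside the model family.
* The generator's temporal shock is stationary and shared across radii;
  directional landscape change (e.g. densification gradients) must be
  supplied by the user through real proportion tables.
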
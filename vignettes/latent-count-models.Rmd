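---
title: "Latent-Gaussian count models for factorial microbiome designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-Gaussian count models for factorial microbiome designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentcount)
```

## The model

`latentcount` fits Bayesian hierarchical models to taxon-by-sample read
counts from factorial silage (ensiling) experiments: grains are rehydrated,
inoculated (a control and two bacterial inoculants), sealed, and the
microbial community is sequenced after fermentation periods of 0, 3, 7, 21,
90 and 360 days, with replicate silos per cell. The observed data are OTU or
taxon read counts `y` with one observation per (taxon, sample) pair.

Counts are modelled through a latent Gaussian field:

    l = X b + Z1 u1 + Z2 u2 + Z3 u3 + Z4 u4 + e
    y_i ~ family(lambda_i = exp(l_i))

where

* `b` holds the systematic effects: intercept, fermentation-period
  contrasts and inoculant contrasts (reference coding; reference = first
  observed period and CTRL). Reference coding is essentially arbitrary under
  the flat N(0, 1e8) prior on `b`, but gives interpretable contrasts.
* `u1` is a taxon (species) effect, `u2` taxon-by-period, `u3`
  taxon-by-inoculant and `u4` taxon-by-period-by-inoculant; each block k
  has `u_k ~ N(0, sigma2_k I)` with `sigma2_k ~ IG(alpha_k/2,
  alpha_k beta_k/2)`.
* `e ~ N(0, sigma2_e I)` is a log-scale error giving per-observation
  overdispersion relative to the Poisson.

Observation families: `poisson`, zero-inflated Poisson (`zip`), hurdle
(alias `zap` — in the count literature "zero-altered Poisson" and "hurdle"
name the same family, so the package implements two distinct zero-modified
families rather than inventing a third), and `normal` as a raw-scale
baseline with identity link. For `normal` the response is modelled directly
as `y = Xb + sum Z_k u_k + e` — no latent layer — so `sigma2_e` is the
observation variance. The zero probability `pi` in `zip`/`hurdle` is a
single scalar with a Beta prior; no covariate structure is assumed for it.

Grain is deliberately not a model term: corn and sorghum are analysed with
separate fits (the workflow layer loops over grains), mirroring how such
factorial silage studies tabulate the two grains separately.

Each taxon granularity (OTU, genus aggregate, ...) is accepted as-is; the
model is agnostic to what the `taxon_id` labels denote.

## Priors and their defaults

Block hyperparameters default to `alpha_k = beta_k = 0.001` for `u1..u4`
and `alpha_e = 0.001, beta_e = 1e8` for the error. Note that
`alpha_e * beta_e / 2 = 5e4` enters the inverse-gamma full conditional as a
constant, so at small n this default is strongly informative and pins
`sigma2_e` near `1e5 / n`; it is retained as the documented default, but
every simulation study in this package's tests overrides it with the weak
`alpha_e = beta_e = 0.001` — a ground truth of `sigma2_e = 0.25` can only
be recovered under a prior that does not overwhelm a few hundred
observations. Pass `hyper = list(e = c(0.001, 0.001))` to `model_spec()`
for the weak prior.

## Sampling

`run_chain()` runs a Metropolis-within-Gibbs sweep: latent vector, fixed
effects, each random-effect block, all variance components, then the zero
layer (`zip`/`hurdle`). Everything except the latent sites is conjugate and
sampled exactly (Gaussian blocks via Cholesky factorizations of the
precision, never an explicit inverse; variances from their inverse-gamma
full conditionals; `pi` from beta-binomial conjugacy). The latent
conditional under a count family is non-conjugate, so each site gets a
random-walk Metropolis update targeting
`family(y_i | l_i, pi) * N(l_i | mu_i, sigma2_e)`; site-wise independence
holds because the error covariance is diagonal. A pure Gibbs scheme is not
available for this conditional — Metropolis-within-Gibbs is the minimal
faithful extension.

Proposal scales adapt per site during burn-in by Robbins-Monro toward an
acceptance rate of 0.44 (the scalar random-walk optimum) and are frozen
afterwards, preserving the correct invariant distribution. Initialization
is neutral: intercept from `log(mean(y) + 0.5)`, zero effects, unit
variances, `l = log(y + 0.5)`, `pi` = observed zero fraction. An all-zero
count vector under Poisson proceeds with a warning (the posterior simply
concentrates at small lambda).

The default `sampler_config()` reproduces the full published protocol —
2,000,000 sweeps, 100,000 burn-in, thinning 10 — while tests and examples
use chains of 10^3–10^4 sweeps on problems of a few hundred observations,
where the conjugate structure makes mixing fast. In ZIP fits, sites with a
structural-zero indicator keep their Metropolis update with zero likelihood
weight, so their target collapses to the Gaussian prior; `e` is kept
implicit as `l - Xb - sum Z_k u_k`, which matches the model algebraically.
`u4` and `e` are weakly identified without replication: with one
observation per (taxon, period, inoculant) cell their variances separate
only through the prior.

## Model selection

`compute_dic()` reports `Dbar`, `Dhat` at posterior means, `pD = Dbar -
Dhat` and `DIC = Dbar + pD`, with two conditioning variants:

* **conditional-on-latent** (default): deviance as a function of the
  retained latent draws. Cheap, and the natural summary of a single fit.
* **marginal** (`conditioning = "marginal"`): deviance as a function of
  `(b, u, sigma2_e, pi)` with the log-scale error integrated out by 20-node
  Gauss-Hermite quadrature, i.e. the observation model becomes the
  Poisson-log-normal (or its zero-modified variant).

The distinction matters. Under the conditional variant the per-observation
latent can absorb arbitrary lack of fit at zero deviance cost — structural
zeros included — because the deviance never sees the latent prior. In
simulation, plain Poisson then dominates zip/hurdle even on data with 40%
structural zeros, and hurdle can edge out Poisson on pure Poisson data
through its zero-truncation term. The marginal variant charges the model
for the latent variance it uses, and family selection behaves as expected:
the generating family wins. `workflow_compare()` therefore defaults to the
marginal variant for family screening, while the conditional variant
remains available and is flagged in every report (`variant` field). Which
conditioning the original analysis protocol used is not identifiable from
its description.

Structure search over random-effect blocks respects marginality
(`candidate_structures()`): u2/u3 require u1, u4 requires u2 and u3 — six
candidates. `select_model()` picks the smallest DIC, breaking ties toward
fewer blocks, then lexicographic family order.

Convergence is checked with Geweke's diagnostic (`geweke_z()`): the means
of the first 10% and last 50% of each scalar chain are compared with a z
statistic whose window variances are spectral densities at zero, estimated
by an AIC-selected AR fit per window (standard Geweke practice). The window
fractions are the conventional defaults.

## Posterior summaries and mean separation

`cell_summary_table()` reproduces the layout of factorial abundance tables:
one posterior mean and CV per (inoculant, period) cell, compared either as
inoculants-within-period or periods-within-inoculant. Per cell, each
retained draw combines the fixed-effect part with the balanced average over
taxa of the included random-effect contributions — tables report one number
per cell despite taxon-level effects, and the balanced average is the
interpretive choice made here. Summaries default to the response (count)
scale, applying `exp` draw-wise (so response means exceed exponentiated
latent means, by Jensen); latent-scale output is available for diagnostics.
The CV is the sample standard deviation (n-1) of the retained draws over
their mean.

Two cells differ when the equal-tailed 95% credibility interval of their
draw-wise difference excludes zero — equal-tailed rather than HPD, as the
simplest reading of a credibility-interval rule; letters then come from an
insert-and-absorb compact letter display (cells sorted by descending mean;
two cells share a letter iff not flagged different). No multiplicity
adjustment is applied beyond the interval rule itself; with three
inoculants per period column the null any-flag rate per column is
therefore around 10%, as for any unadjusted triple of 5%-level dependent
comparisons.

## The synthetic generator

`simulate_dataset()` draws data from exactly the model above, with known
ground truth: block effects from their Gaussian laws, the latent field,
then counts from the chosen family. ZIP zeroing is applied as a
structural-zero mixture after the count draw; hurdle draws a zero with
probability `pi_zero` and otherwise a zero-truncated Poisson via
inverse-CDF. One root seed drives deterministic per-stage streams. Presets
(`scenario()`): `corn-like` and `sorghum-like` use the full 3-inoculant by
6-period by 3-replicate grid with 6 taxa and baseline abundances of ~5 and
~22 reads (the scale of bacterial abundance tables in such studies), taxon
heterogeneity `sigma2_u1 = 1` and log-scale error 0.25; `zero-heavy` adds
a structural-zero fraction of 0.4 to exercise zero-modified selection;
`null` zeroes every effect and variance.

What the generator does *not* emulate: taxon-taxon correlation,
compositional (fixed-depth) constraints, sequencing error or chimeras, and
real depth variation (a per-sample offset is deliberately absent because
the fitted model has no offset term). Passing recovery tests on this
generator shows the inference machinery is correct for its own model; it
does not validate the model against those features of real sequencing data.

## Diversity and depth standardization

`alpha_diversity()` reports, per sample, Chao1 richness (classic form
`S_obs + F1^2/(2 F2)`; the bias-corrected branch is used when `F2 = 0` to
avoid division by zero), Pielou evenness (Shannon entropy over log observed
richness — undefined for single-taxon samples) and Gini-Simpson diversity
`1 - sum p_i^2`. "Simpson diversity" and "evenness" are ambiguous labels in
the field, so the inverse-Simpson and Simpson-evenness variants sit behind
flags. Depth standardization subsamples each sample without replacement to
a common depth (`rarefy_counts()`); expected richness under subsampling is
computed in closed form from the hypergeometric miss probabilities
(`rarefaction_curve()`), which is exact, non-decreasing and concave, with a
Monte-Carlo path for cross-checking.

## Numerical choices and test problem sizes

All likelihoods are evaluated in log space and stay finite over latent
values spanning dozens of orders of magnitude; the ZIP zero mass uses
log-sum-exp, and zero-truncation uses `log(-expm1(-lambda))`. The
Metropolis kernel drops `log(y!)` terms, which cancel in the acceptance
ratio. Cholesky factorization backs every Gaussian draw; incidence blocks
use the diagonal of `Z'Z` directly via segment sums.

Simulation studies in the test suite use the full factorial grid (6 taxa,
3 inoculants, 6 periods, 3 replicates; n = 324) for recovery and size
control, a 3-period grid (n = 162) for family screening, and chains of
8,000–20,000 sweeps — sizes at which the conjugate structure mixes well and
twenty replicate fits complete in minutes. Family screening fits all
candidate families with a common seed (common random numbers) so that
chain-level Monte-Carlo error partially cancels in DIC differences.

## Known limitations

* Single-chain inference with Geweke diagnostics; no multi-chain R-hat.
* Scalar `pi`: zero inflation cannot vary with covariates.
* The conditional-on-latent DIC should not be used to compare observation
  families (see above); use the marginal variant.
* `u4` and `e` variances separate only through the prior when cells are
  unreplicated at the (taxon, period, inoculant) level.
* Chao1 depends on singleton/doubleton counts and is not scale-invariant;
  rarefy to a common depth before comparing it across samples.
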
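---
title: "Methods: scenario-based projection of county under-five mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scenario-based projection of county under-five mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(u5mproj)
```

## The problem

Subnational health planning needs forward projections of under-five
mortality (U5M, deaths among children under five per 1,000 livebirths)
under alternative intervention scale-up policies. `u5mproj` implements
such a pipeline for a panel of counties observed over a baseline window
(by default 47 counties, 2003–2014, matching the shape of Kenya's
devolved health system): it relates log U5M to intervention coverage
through a Bayesian spatio-temporal ecological model, extrapolates
coverage under business-as-usual (BAU) and four scale-up scenarios, and
converts the coverage gaps into counterfactual mortality paths and
SDG 3.2 attainment counts (target: U5M strictly below 25/1,000 by
2022/2025).

Because the survey-derived county panel behind such analyses is not
publicly deposited, the package ships a synthetic-data generator with
the same statistical structure and known ground truth; every
simulation-based claim in the test suite is made against that
generator, not against real data.

## Rate arithmetic

All projections rest on the annual rate of change (ARC) between two
positive values $n$ years apart,

$$\mathrm{ARC} = \frac{100}{n}\,\ln\!\frac{y_{t+n}}{y_t},$$

and its inverse, exponential projection
$y_{t+k} = y_t e^{\mathrm{ARC}\cdot k/100}$. The two functions are
exact inverses; the suite checks the round trip to $10^{-9}$ relative
error.

**Year-count convention.** $n$ is the plain year difference: 2003 to
2014 is 11 annual steps, 2014 to 2022 is 8, 2022 to 2025 is 3. Printed
summaries of this kind of analysis are not always internally consistent
about $n$; we fix the unambiguous difference convention throughout and
expose $n$ as an explicit argument to `arc()`.

**Coverage bounds.** Projected coverage proportions are clamped to
$[0.001, 0.99]$. The ceiling is the universal-coverage cap used by the
scale-up rules ("99% by 2025"); the floor keeps logarithms finite.
Inside files coverage is stored in percent; in memory it is always a
proportion in $(0,1)$ — the regression coefficients below are therefore
per unit-proportion change (a coefficient of $6.59$ for HIV prevalence
means $e^{6.59}$ per 100-percentage-point change, which is the only
plausible reading of effects of that magnitude).

## The spatio-temporal model

For county $i$ and year $t$,

$$\log\!\left(\frac{\mathrm{U5M}_{i,t}}{1000}\right) = \alpha +
\sum_k \beta_k x_{k,i,t} + w_i + \nu_i + \phi_t + \delta_{i,t},$$

with

* $w$ — structured spatial effect, intrinsic CAR (ICAR) on the county
  adjacency graph, constrained to sum to zero (scale $\sigma_w$);
* $\nu$ — unstructured iid county effect (scale $\sigma_{\nu 1}$);
* $\phi$ — first-order random walk over years, sum-to-zero for
  identifiability with the intercept (scale $\sigma_t$);
* $\delta$ — iid space–time interaction (scale $\sigma_{\nu 2}$),
  which doubles as the residual: the model carries exactly four
  variance components and no separate observation-noise term. This is
  an interpretation choice — a BYM-type spatial pair plus temporal and
  interaction components is the configuration that matches a
  four-component variance table — and the component flags in
  `model_spec()` make the mapping configurable.

Priors are weakly informative and standard for BYM-type models:
$\alpha, \beta_k \sim N(0, 10^2)$ and half-Normal(0, `prior_sd_scale`
$=5$) on each scale.

### Sampler design

The posterior is explored by Metropolis-within-Gibbs, with two design
choices that matter for Monte Carlo efficiency:

1. **Eigenbasis representation.** The ICAR and RW1 fields are
   parameterised in the eigenbasis of their structure matrices (graph
   Laplacian; path-graph Laplacian). The improper priors become
   independent normals on the non-null eigendirections, and the
   sum-to-zero constraints hold exactly by construction (the suite
   checks $|\sum_i w_i| < 10^{-10}$ at every retained draw).

2. **Collapsed blocks.** All location parameters (intercept, fixed
   effects, spatial and temporal coefficients) are drawn *jointly*
   from their conjugate multivariate-normal full conditional, with the
   iid county effect integrated out analytically (its covariance
   contribution is a rank-one term per county). The four scales are
   updated by random-walk Metropolis on the log scale against the
   *marginal* likelihood with the entire location vector integrated
   out — a closed-form evidence obtained from the same Cholesky factor
   the location draw uses. Updating scales against the marginal rather
   than the conditional removes the location–scale coupling that
   otherwise dominates the autocorrelation time, and collapsing the
   iid county effect avoids the near-zero "funnel" that appears when
   that variance component is small.

Metropolis step sizes adapt in batches of 50 iterations during burn-in
only (targeting roughly 44% acceptance), preserving ergodicity of the
post-burn-in chain. Three scale sweeps run per iteration; each proposal
costs one Cholesky factorisation of a dense matrix of dimension
$1 + K + (n-1) + (T-1)$ (117 for the default panel), so the extra
sweeps are cheap and keep the scale parameters' Monte Carlo error well
inside the diagnostics gate.

Chains are initialised overdispersed (chain-indexed displacement of
scales and locations) and run under seeds `seed + chain - 1`, making
every fit exactly reproducible.

### Diagnostics

`summarize_posterior()` reports, per parameter: pooled posterior mean,
empirical 2.5/97.5% quantiles, SD, Monte Carlo standard error by batch
means (batch size $\lfloor\sqrt{N}\rfloor$ per chain, pooled as the
variance-average across chains), and the Gelman–Rubin statistic on the
percentage scale $(\widehat{R}-1)\times 100$. Two conventions:

* $\widehat R$ is floored at 1, so two identical chains report exactly
  0% (the raw two-chain PSRF is $\sqrt{(n-1)/n} < 1$ when the
  between-chain variance is zero);
* degenerate constant chains report 0 for SD, MC error and Gelman.

`check_convergence()` passes a parameter when both its Gelman
statistic and its MC-error/SD ratio are below 5% (configurable), and
the fit overall when every fixed effect and variance component passes.
The suite cross-checks the Gelman statistic against
`coda::gelman.diag()` (which applies an additional degrees-of-freedom
correction, hence agreement to a few percent rather than exactly).

### Post-fit pruning

`prune_nonsignificant()` iteratively removes the factor whose 95%
credible interval contains zero and whose posterior mean is most
centred on zero (smallest $|\text{mean}|/\text{SD}$), refitting after
each removal until all retained intervals exclude zero or only the
intercept remains. One factor moves per refit because removals change
the remaining coefficients.

## Factor selection

The selection pipeline mirrors common epidemiological practice for
reducing a candidate set of coverage indicators before a multivariable
fit:

1. **Bivariate screen** — pooled county-year OLS of log U5M on each
   factor alone, kept when the two-sided Wald p-value is below 0.2.
   The pooled fit deliberately ignores spatial correlation: the screen
   is a permissive filter, not an inference.
2. **Redundancy exclusion** — factors whose contribution an umbrella
   indicator captures (e.g. individual vaccines vs. fully-immunised
   status) are dropped when the umbrella itself screened in; cyclic
   maps are rejected.
3. **ANC index** — the three interventions delivered during antenatal
   visits are collinear with visit coverage; model 2 replaces them
   with the first principal component of their standardised values,
   oriented positively against the component mean and rescaled to
   mean 0, SD 1.
4. **Elastic net** — penalised least squares over an
   $(\alpha, \lambda)$ grid, scored by k-fold cross-validated MSE.
   Folds group whole counties so years of one county never straddle
   the train/test split (pooled rows of one county are strongly
   dependent). Standardisation uses panel-wide means/SDs computed once
   before cross-validation — simpler and deterministic, at the cost of
   a small optimistic bias that is irrelevant for model *comparison*.
   Ties in CV MSE resolve to the smaller penalty; the model-1/model-2
   comparison resolves ties to model 1 (no derived variable).

The suite verifies the screen's type-I rate against its nominal level,
the unpenalised and fully-shrunk limits of the elastic net, and exact
soft-threshold equivalence on orthonormal designs.

## Scenario engine

Coverage trajectories for 2015–2025 are built per factor from the 2014
baseline:

* **BAU** — each county continues its own 2003–2014 ARC.
* **Scenario 1** (best county) — the factor's target is the best
  county's 2014 value (maximum; minimum for prevalence-type factors
  where lower is better, with ties to the lowest county id). One
  national ARC, from the national 2014 mean to the target over 8
  steps, applies to every county's own baseline. Counties whose
  projected 2022 value reaches the target (within $10^{-9}$ or beyond,
  in the improvement direction) switch to an ARC attaining 99% by
  2025; decreasing-good factors never switch and simply continue
  (the universal-coverage rule is defined for coverage-type
  indicators, not prevalences).
* **Scenario 2** (fastest observed rate) — the single fastest
  improvement-signed county ARC of 2003–2014 applies everywhere for
  the whole period.
* **Scenario 3** (national projection) — the national county-mean
  series sets a national ARC; the implied period ARCs (2015–2022,
  2022–2025) apply to each county's own baseline, so trajectories
  still differ by county.
* **Scenario 4** (policy targets) — national ARCs from the 2014
  national mean to the 2022 target and from the 2022 to the 2025
  target, applied to county baselines. Default targets ship in
  `default_factor_meta()`.

"National" coverage is the unweighted county mean throughout:
livebirth weights are not part of the panel contract, and the
unweighted mean keeps every scenario a pure function of the panel.
Whether a shared scale-up rate should be computed from the national
mean or per county is genuinely ambiguous in verbal descriptions of
such scenarios; the national-baseline reading is implemented because
it makes scenario 1's "shared rate" property exact (every county's
2022/2014 ratio is identical), which is also what makes it testable.

## Counterfactual prediction

BAU mortality continues each county's own 2003–2014 U5M ARC. Because
the model is log-linear and the random effects are county-year
constants shared by both coverage paths, the counterfactual under a
scenario is a multiplicative adjustment, not a full re-prediction:

$$\mathrm{U5M}^{s}_{i,t} = \mathrm{U5M}^{\mathrm{BAU}}_{i,t}
\exp\!\Big(\sum_k \beta_k\,(x^{s}_{k,i,t} - x^{\mathrm{BAU}}_{k,i,t})\Big).$$

This has three exact consequences the suite asserts: the null
counterfactual returns BAU unchanged; per-factor impacts add on the
log scale to the joint impact (to $10^{-12}$); and for a beneficial
factor ($\beta_k < 0$) more coverage never increases mortality. Point
predictions use posterior-mean $\beta$; the draw set is retained in
`coefficient_set()` for interval propagation when wanted. Percent
change is reported relative to BAU (an alternative relative-to-2014
reading exists for such figures; relative-to-BAU is the definition
used by the attainment summaries here).

SDG 3.2 attainment is strict: a county at exactly 25.0 deaths/1,000
has not attained the target. Attainment percentages are
$100\,\cdot\,\text{count}/n_{\text{counties}}$ rounded to one decimal.

## The synthetic-data generator

`simulate_panel()` emulates the features the analysis relies on:

* coverage follows per-county constant-ARC exponential paths, clipped
  to $(0.001, 0.999)$ — matching the projection arithmetic, rather
  than logistic curves;
* log U5M follows the model above exactly, with $w$ drawn from the
  ICAR law on a synthetic adjacency graph (eigendecomposition of the
  Laplacian with the null direction removed, then centred), $\phi$ a
  centred Gaussian random walk, and $\nu,\delta$ iid normal;
* U5M is lognormal given the covariates — the noise family implied by
  a log-linear mean model, adopted because ecological U5M estimates
  of this kind come without a stated likelihood.

Defaults are the study conditions: 47 counties, years 2003–2014, the
ten retained factors with their fitted posterior means as true
coefficients (`default_true_beta()`), and variance components
$\sigma_w = 0.5336$, $\sigma_{\nu1} = 0.0024$, $\sigma_t = 0.0591$,
$\sigma_{\nu2} = 0.1398$. Coverage starts are drawn from $(0.10,
0.85)$ with ARCs in $(-3, 8)$%/year — a plausible range for
intervention scale-up over that era — except HIV prevalence, which
starts in $(0.01, 0.12)$ with ARCs in $(-9, 1)$%/year to emulate a
low, declining prevalence. The adjacency graph joins jittered grid
points to their nearest neighbours and connects components, giving a
planar-like, connected neighbour structure.

What the generator does *not* emulate: real geography or county
identities, survey sampling error and its spatial smoothing, reporting
gaps, or correlation between factors beyond what the shared random
effects induce. Passing recovery tests therefore demonstrates internal
correctness of the estimator under the stated model, not robustness to
the messiness of real survey panels.

## Test and problem sizes

The suite runs the full recovery check at the study shape (47 counties
× 12 years × 10 factors) with 2 chains × 3,000 iterations (1,000
burn-in) — the package's test-scale MCMC configuration
(`mcmc_config_test()`); the analysis-scale default is 2 × 25,000 with
5,000 burn-in (`mcmc_config()`). Smaller structural tests use panels
of 5–30 counties. Monte-Carlo contracts (screen type-I rate,
model-pair recovery) use 10–200 replicates under fixed seeds. With the
blocked sampler, interval coverage of the ten true coefficients is
expected to fluctuate around its nominal level across generator seeds;
individual seeds can fall a draw or two below, which is sampling
variation of the simulated truth, not estimator bias.

## Known limitations

* The ecological model supports associational, not causal, readings;
  counterfactuals inherit that caveat.
* Linear effects of coverage on log mortality assume scale-up is
  equally effective at any baseline level.
* ARC extrapolation over 11 years compounds any misestimation of the
  baseline trend; no uncertainty is attached to the ARC projections
  themselves.
* The iid interaction term doubling as residual means "interaction"
  and "noise" are not separately identified.
* National aggregation is unweighted; with strongly unequal county
  birth cohorts a weighted mean would differ.
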
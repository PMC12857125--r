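---
title: "Methods: Bayesian intersectional MAIHDA with a skewed outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian intersectional MAIHDA with a skewed outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maihda)
```

## The model and its assumptions

MAIHDA treats intersectional strata — here the 108 cells of the
sex × race/ethnicity × age × education cross-classification of
`nhis_design()` — as level-2 units of a random-intercept model. For a binary
current-drinker outcome,

$$\operatorname{logit} \Pr(y_{ij}=1) = \mathbf{x}_{ij}'\boldsymbol\beta + u_j,
\qquad u_j \sim N(0, \sigma_u^2),$$

and for the positive, strongly right-skewed consumption of drinkers
(grams/day, capped at 200 g),

$$\log(\text{gpd}_{ij}) = \mathbf{x}_{ij}'\boldsymbol\beta + u_j + e_{ij},
\qquad e_{ij} \sim N(0, \sigma_e^2).$$

The *null* model has an intercept only, so $\sigma_u^2$ captures all
between-stratum variation and the intercept converges to the
precision-weighted grand mean of stratum means. The *main-effects* model adds
one contrast per non-reference category level (references: Men, White,
21–24, low education) and survey-year dummies; its $u_j$ then represents
pure *interaction* structure — whatever the additive combination of
positions cannot explain. The random-intercept prior induces shrinkage:
each stratum's deviation is pulled toward the additive prediction in
proportion to $\sigma_e^2 / n_j$, which is what makes estimates for tiny
strata (real survey strata range from a handful to tens of thousands of
respondents) stable. Assumptions worth keeping in view: exchangeable normal
stratum effects, a common residual variance across strata, and no
within-stratum covariates beyond the survey year.

Estimation is unweighted, matching the practice of fitting these models by
MCMC (which does not naturally accommodate survey weights).

## Priors and samplers

"Diffuse" priors are made concrete as $\beta_k \sim N(0, 1000^2)$
independently, and an inverse-gamma(0.001, 0.001) prior on each free
variance; `maihda_mcmc(variance_prior = "uniform_sd")` selects a uniform
prior on the standard deviation instead (drawn by inverse-CDF from the
truncated conditional). Defaults are 2 chains of 5,000 iterations with
2,500 burn-in, thin 1.

Both samplers operate on data collapsed to stratum × year cells, since rows
within a cell share an identical design-matrix row; cell counts, outcome
sums and sums of squares are sufficient. This makes cost independent of the
number of individuals.

* **Linear family**: conjugate Gibbs — multivariate normal for
  $\boldsymbol\beta$, independent normals for $u_j$, inverse-gamma for both
  variances.
* **Logistic family**: Polya-Gamma augmentation. Cell-level augmentation
  variables $\omega_c \sim \mathrm{PG}(n_c, \eta_c)$ render all conditionals
  Gaussian. `rpg()` draws PG variates by the exact-in-distribution gamma
  convolution (200 terms, deterministic tail-mean correction) for counts
  below 30 and by a moment-matched normal approximation above, where the CLT
  error is negligible; `pg_mean()`/`pg_var()` expose the analytic moments the
  sampler and its tests rely on. The individual-level variance of the
  logistic family is not a free parameter; the latent-response constant
  $\pi^2/3 \approx 3.29$ is stored in its place.

Random-intercept models of this kind mix poorly in the raw parameterization
because the intercept and the mean of the $u_j$ are only jointly identified.
Each iteration therefore ends with a parameter-expansion (ASIS) recentering
step: a shift $\mathbf{c}$ along the stratum-level fixed-effect directions is
drawn from its exact conditional under the priors and applied as
$\boldsymbol\beta \mathrel{+}= \mathbf{c}$, $u_j \mathrel{-}= \mathbf{x}_j'\mathbf{c}$,
which leaves the posterior invariant and removes the random walk. With it,
effective sample sizes for fixed effects are in the thousands per 2,000
draws.

Convergence is monitored per parameter with the split-chain $\widehat R$ and
an initial-positive-sequence effective sample size; a fit is *flagged* (with
a warning, never silently accepted) when $\widehat R > 1.05$ or ESS < 200.
`blup_shrinkage()` provides the closed-form shrunken stratum means for a
linear null model with known variances; the test suite requires posterior
mean $u_j$ from the sampler (variances fixed at truth) to correlate with
this independent oracle above 0.99.

## Variance partition and stratum decomposition

The VPC is computed per posterior draw as
$\sigma_u^2 / (\sigma_u^2 + \sigma_e^2)$ and averaged; the PCV pairs null and
main draws index-wise as $(\sigma^2_{u,\text{null}} -
\sigma^2_{u,\text{main}}) / \sigma^2_{u,\text{null}}$. A plug-in mode
(posterior-mean variances into the same formulas) is provided because
summaries computed from unrounded draws and from rounded point estimates can
differ in the last digit (e.g. 16.8% vs 16.9% for stratum variance 0.67
against $\pi^2/3$); the mode used is recorded in the result.

Stratum predictions are evaluated at a single reference year (2009 by
default) rather than averaged over years. For each draw $d$ and stratum $j$:
$\eta^{\text{add}}_{jd} = \mathbf{x}_j'\boldsymbol\beta_d + \text{year
effect}$, $\eta^{\text{tot}}_{jd} = \eta^{\text{add}}_{jd} + u_{jd}$, both
mapped to the outcome scale (inverse logit × 100, or the log-normal mean
back-transformation below). The interaction effect is the *per-draw*
difference; its credible interval is the 2.5–97.5 percentile range of those
differences, not interval arithmetic — necessary for the significance flags
to be meaningful.

Point estimates are posterior **means**, not medians: the mean is the only
summary under which the decomposition identity
`total = additive + interaction` carries over exactly from the per-draw
level to the reported table, and that identity is a contract of the output
(intervals remain percentile-based). Had medians been used, the three
summary columns would not sum.

## Back-transformation of the skewed outcome

Consumption is modelled as log-normal, so the stratum mean on the original
scale is $\exp(\eta + \sigma_e^2/2)$, applied per draw with that draw's
$\sigma_e^2$ and summarized afterwards. As $\sigma_e^2 \to 0$ this reduces
to $\exp(\eta)$, a limit the tests pin down. Where log-normality of
residuals is doubted, `backtransform_lognormal(..., smear = f)` accepts a
nonparametric smearing factor (the mean of exponentiated residuals) in place
of the parametric factor. The log-normal mean retransformation is the
standard choice consistent with the fitted model; it is sensitive to
departures from normality in the log-scale residuals, which is the main
caveat when applying the pipeline to real data.

## The synthetic-cohort generator

`simulate_cohort()` is the model's inverse and defines the study conditions
under which everything here is validated. It emulates: the 108-stratum
design; drinker status from the two-level logistic model; drinkers'
grams/day as $\exp(N(\eta, \sigma_e^2))$ with its own stratum effects,
capped at 200 g; survey years drawn uniformly over a configurable range
(year effects default to zero); uniform ages within age bands (top-coded at
85); and per-field missingness injection for exercising the exclusion
filters. Default generating coefficients (`default_truth_status()`,
`default_truth_gpd()`) mirror the magnitudes estimated for US adults — e.g.
a −0.55 log-odds women contrast for drinking status, a −0.98 log-scale women
contrast for consumption, null-model stratum variances 0.67 and 0.41, and
residual variance 2.98.

Randomness is split into separate streams for allocation, stratum effects
and outcomes, so changing one rate leaves the other draws untouched, and
identical seeds give byte-identical cohorts. Allocation is equal-per-stratum
by default so all 108 strata are populated; a `"skewed"` preset reproduces
the four-orders-of-magnitude imbalance of real survey strata for shrinkage
experiments, and arbitrary weights are accepted.

Two u-draw modes exist, decided up front: `"iid"` (the default) draws
stratum effects independently, so their realized variance is itself a random
quantity; `"orthogonal"` residualizes the realized effects against the
stratum-level main-effects design and rescales them to the exact nominal
variance. The orthogonal mode is the appropriate one for known-truth
parameter-recovery experiments — it makes "generated with stratum variance
$v$" literally true of the realized cohort and prevents finite-$J$ leakage
of stratum effects into fixed-effect estimates — and it is what the
acceptance script uses.

What the generator does *not* emulate: survey weights and household
clustering, the quantity–frequency derivation of grams/day from raw survey
items (consumption is drawn directly), item-level response processes behind
missingness, and any within-stratum covariate structure. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated generating model, not robustness to the messiness of real survey
data.

## Problem sizes and numerical choices

Test and validation runs use deliberately sized problems: recovery of the
women contrasts uses 40,000–100,000-person cohorts with 2,000–3,000
iterations; the null-model VPC experiment uses 108 strata × 600; interval
coverage is checked over 40 replicates of 2,160-person cohorts; the
acceptance script (`scripts/acceptance.R`) uses 100,000-person cohorts and
3,000-iteration chains. These sizes put Monte-Carlo error well inside the
tolerances being checked while keeping a full run to minutes on one core.

Other numerical choices: variance draws are floored at $10^{-10}$ to avoid
degenerate conditionals; the PG series/normal switch is at count 30;
ranked-strata tables break ties by stratum index; interaction ranking
considers only significant interactions unless asked otherwise; the
between-outcome residual SD uses the population formula (divide by $n$) by
default with an `"n-2"` option, the choice being recorded in the output; and
outlier flagging adds a $10^{-10}$-scale epsilon so perfect fits are not
flagged on floating-point noise. Empty strata receive prior draws of $u_j$
(full shrinkage toward the additive prediction) and are excluded from the
variance update.

## Known limitations

* Two levels only — no cross-classified or three-level extensions, and no
  model-comparison machinery.
* The logistic normal approximation for large PG counts trades a negligible
  distributional error for speed; exact samplers for all counts would be
  needed for micro-level posterior functionals far in the tails.
* PCV pairing of null and main draws is index-wise across independently run
  chains; it is a convenience pairing of two independent posteriors, not a
  joint posterior.
* Real-data ingestion stops at a documented CSV schema; parsing survey
  fixed-width extracts and re-deriving race/ethnicity recodes from raw
  items are out of scope (a simple two-column combiner plus the documented
  axis levels suffice for prepared data).
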
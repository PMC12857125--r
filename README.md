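# maihda

Bayesian **Multilevel Analysis of Individual Heterogeneity and Discriminatory
Accuracy (MAIHDA)** for intersectional health disparities, with first-class
support for skewed outcomes.

## The problem this package addresses

Alcohol consumption in the US is patterned by sex, race and ethnicity, age,
and education — but these positions do not act in isolation. Inter-categorical
intersectional analysis asks how they *combine*: which intersectional groups
drink more or less than the additive combination of their social positions
would predict? This package implements the MAIHDA approach to that question
for two outcomes: a binary current-drinker indicator and, among drinkers,
average consumption in grams of pure alcohol per day (GPD) — a strongly
right-skewed quantity modelled on the log scale and back-transformed.

It is aimed at social epidemiologists and quantitative intersectionality
researchers who want a tested, reproducible MAIHDA pipeline with a built-in
synthetic-cohort generator for method validation (the real survey microdata
cannot be redistributed, so every analysis here is exercised on simulated
NHIS-like cohorts with known generating truth).

## The model

Individuals *i* are nested in *j* = 1, …, 108 intersectional strata, the
cells of a 2 (sex) × 6 (race/ethnicity) × 3 (age group) × 3 (education)
cross-classification. For drinker status:

```
logit Pr(y_ij = 1) = x_ij' beta + u_j,   u_j ~ N(0, sigma_u^2)
```

and for log consumption of drinkers (GPD capped at 200 g ≈ 14 standard
drinks):

```
log(gpd_ij) = x_ij' beta + u_j + e_ij,   e_ij ~ N(0, sigma_e^2)
```

where `x_ij` is empty (null model) or holds main-effect contrasts for the
four axes plus survey-year dummies (main-effects model). Estimation is MCMC
with diffuse priors: conjugate Gibbs for the linear family, Polya-Gamma
augmentation for the logistic family, plus a parameter-expansion recentering
step for fast mixing.

Key derived quantities:

* **VPC** (variance partition coefficient): `sigma_u^2 / (sigma_u^2 + sigma_e^2)`,
  with `sigma_e^2 = pi^2/3 ≈ 3.29` for the logistic family (latent-response
  formulation). The discriminatory accuracy of the stratification.
* **PCV** (proportional change in variance):
  `(sigma_u^2[null] − sigma_u^2[main]) / sigma_u^2[null]` — how much of the
  between-stratum variance the additive main effects explain.
* **Stratum predictions**: for each stratum and posterior draw, the additive
  prediction (fixed effects only) and the total prediction (fixed effects +
  shrunken stratum effect) on the outcome scale; their per-draw difference is
  the **interaction effect**, with 95% credible intervals and significance
  flags. For GPD, predictions use the log-normal mean back-transformation
  `exp(eta + sigma_e^2/2)` per draw.

## Worked example

```r
library(maihda)

cohort <- simulate_cohort(54000, years = 2005:2012, seed = 42)
m <- maihda(drinker ~ sex + race_ethnicity + age_group + education,
            data = cohort, family = "binomial", design = nhis_design(),
            mcmc = maihda_mcmc(iter = 2500, burn_in = 1000, seed = 42))
print(m)
```

```
Intersectional MAIHDA analysis (binomial family)
  outcome: drinker; n = 54000 individuals in 108/108 strata
  predictions at year 2009
Variance partition (binomial family, mode = draws)
  stratum variance: null 0.672, main 0.0587
  individual variance: 3.29
  VPC: null 16.9%, main 1.8%; PCV 91.1%
  significant interactions: 26/108 strata
```

The cohort was generated from the package's default truth (stratum variance
0.67 in the null representation); the fitted null-model VPC of 16.9% says
that roughly a sixth of the latent variation in drinking propensity lies
*between* intersectional strata, and the PCV of 91.1% says additive main
effects absorb most — but not all — of it: the remainder is interaction
structure. Ranked stratum tables show who sits at the extremes:

```r
rank_strata(m$predictions, k = 3, mode = "highest")[, c("label", "total", "interaction")]
```

```
                    label total interaction
    M, 21-24, Asian, high  86.8         1.3
  M, 25-59, White, medium  86.5         5.0
    M, 21-24, White, high  84.9        -2.6
```

(`total` is the posterior-mean percentage of current drinkers; `interaction`
is the part not explained by additive effects, in percentage points.)
`plot(m)` draws the caterpillar plot of total vs additive-only predictions;
`correlate_outcomes()` relates the two outcomes across strata with 2-SD
outlier flagging; `run_pipeline("config.yaml")` drives the whole chain from
a config file and writes CSV/JSON/PNG outputs plus a digest manifest.

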
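test_that("Polya-Gamma draws match the analytic moments in both regimes", {
  set.seed(101)
  for (b in c(1, 8, 60)) {        # gamma-series (1, 8) and normal (60) branches
    for (z in c(0, 1.2, 3)) {
      x <- rpg(rep(b, 20000), z)
      se_m <- sqrt(pg_var(b, z) / 20000)
      expect_lt(abs(mean(x) - pg_mean(b, z)), 6 * se_m)
      expect_lt(abs(var(x) / pg_var(b, z) - 1), 0.1)
      expect_true(all(x > 0))
    }
  }
  expect_equal(rpg(0, 2), 0)
  # symmetry in the sign of the tilt
  expect_equal(pg_mean(3, -1.5), pg_mean(3, 1.5))
  set.seed(7); a <- mean(rpg(rep(2, 5000), -2))
  set.seed(7); b2 <- mean(rpg(rep(2, 5000), 2))
  expect_equal(a, b2)
})

test_that("PG moment formulas agree with the zero-tilt closed forms", {
  expect_equal(pg_mean(4, 0), 1)        # b/4
  expect_equal(pg_var(4, 0), 4 / 24)    # b/24
  # continuity across the small-z switch
  expect_equal(pg_mean(1, 1e-4), pg_mean(1, 1.0001e-4), tolerance = 1e-6)
})

test_that("design matrix has one contrast per non-reference level plus year dummies", {
  d <- nhis_design()
  recs <- records_grid(d, years = 2000:2018)
  dm <- maihda_design_matrix(recs, d, model = "main")
  # intercept + 1 sex + 5 race + 2 age + 2 education + 18 year columns
  expect_equal(ncol(dm$X), 29L)
  expect_equal(dm$ref_year, 2000)

  dm0 <- maihda_design_matrix(recs, d, model = "null", year_dummies = FALSE)
  expect_equal(colnames(dm0$X), "(Intercept)")

  # a reference-category record in the reference year: intercept only
  ref <- data.frame(sex = "Men", race_ethnicity = "White", age_group = "21-24",
                    education = "low", survey_year = 2000)
  row <- maihda_design_matrix(rbind(ref, recs[, names(ref)]), d, model = "main")$X[1, ]
  expect_equal(unname(row[["(Intercept)"]]), 1)
  expect_equal(sum(row), 1)
  expect_error(maihda_design_matrix(transform(ref, sex = "X"), d),
               "not in design")
})

test_that("the linear sampler recovers both generating variances", {
  co <- simulate_cohort(108 * 500, outcomes = "gpd", years = 2009, seed = 21,
                        truth_gpd = default_truth_gpd("null"))
  fit <- fit_maihda_model(co, nhis_design(), "lognormal", "null",
                          mcmc = maihda_mcmc(iter = 1500, burn_in = 500, seed = 2))
  expect_true(fit$converged)
  # within 3 posterior SDs of the generating truths 0.41 and 2.98
  expect_lt(abs(mean(fit$sigma_u2) - 0.41), 3 * sd(fit$sigma_u2))
  expect_lt(abs(mean(fit$sigma_e2) - 2.98), 3 * sd(fit$sigma_e2))
})

test_that("the linear sampler recovers main-effect contrasts", {
  co <- simulate_cohort(40000, outcomes = "gpd", years = 2009,
                        u_mode = "orthogonal", seed = 33)
  fit <- fit_maihda_model(co, nhis_design(), "lognormal", "main",
                          mcmc = maihda_mcmc(iter = 1500, burn_in = 500, seed = 3))
  w <- fit$beta[, "sexWomen"]
  expect_lt(abs(mean(w) - (-0.98)), 3 * sd(w) + 0.02)
})

test_that("a zero-variance truth concentrates the stratum variance near zero", {
  truth <- generating_truth("lognormal", default_truth_gpd()$fixed_effects,
                            stratum_sd = 0, residual_sd = sqrt(2.98))
  co <- simulate_cohort(108 * 1000, outcomes = "gpd", years = 2009,
                        truth_gpd = truth, seed = 13)
  # the flag fires legitimately here: sigma_u2 mixes slowly at the boundary
  fit <- suppressWarnings(
    fit_maihda_model(co, nhis_design(), "lognormal", "main",
                     mcmc = maihda_mcmc(iter = 1200, burn_in = 500, seed = 6)))
  expect_lt(quantile(fit$sigma_u2, 0.95), 0.02)
})

test_that("the logistic family pins the individual-level variance at pi^2/3", {
  co <- simulate_cohort(108 * 30, years = 2009, seed = 3)
  fit <- suppressWarnings(
    fit_maihda_model(co, nhis_design(), "binomial", "null",
                     mcmc = maihda_mcmc(iter = 400, burn_in = 200, seed = 1)))
  expect_true(all(fit$sigma_e2 == pi^2 / 3))
  expect_equal(round(fit$sigma_e2[1], 2), 3.29)
})

test_that("closed-form shrinkage behaves at the limits", {
  # lambda = sigma_u2 / (sigma_u2 + sigma_e2 / n): 1/(1 + 4/4) = 0.5
  bl <- blup_shrinkage(rep(c(0, 1), each = 4), rep(c(1, 2), each = 4),
                       sigma_u2 = 1, sigma_e2 = 4)
  expect_equal(unname(bl$lambda), c(0.5, 0.5))
  # n -> large: lambda -> 1; empty stratum: full shrinkage to zero
  bl2 <- blup_shrinkage(rnorm(1e5, 3), rep(1, 1e5), 1, 4, n_strata = 2)
  expect_gt(bl2$lambda[1], 0.999)
  expect_equal(bl2$u[2], 0)
  expect_equal(bl2$lambda[2], 0)
})

test_that("posterior stratum effects match the BLUP oracle on balanced data", {
  set.seed(55)
  J <- 108; nj <- 200
  truth <- default_truth_gpd("null")
  co <- simulate_cohort(J * nj, outcomes = "gpd", years = 2009,
                        truth_gpd = truth, seed = 91)
  fit <- fit_maihda_model(co, nhis_design(), "lognormal", "null",
                          mcmc = maihda_mcmc(iter = 1200, burn_in = 400, seed = 2,
                                             fix_sigma_u2 = 0.41,
                                             fix_sigma_e2 = 2.98))
  oracle <- blup_shrinkage(log(co$gpd), co$stratum, 0.41, 2.98, n_strata = J)
  expect_gt(cor(colMeans(fit$u), oracle$u), 0.99)
  # the null intercept sits at the precision-weighted grand mean
  expect_lt(abs(mean(fit$beta[, 1]) - oracle$mu), 0.05)
})

test_that("|posterior stratum effect| is non-decreasing in stratum size", {
  d <- toy_design()
  n_j <- c(2, 8, 32, 128)
  lab <- d$strata[, c("sex", "education")]
  rows <- do.call(rbind, lapply(1:4, function(j)
    cbind(lab[rep(j, n_j[j]), ], gpd = exp(1), survey_year = 2009)))
  lo <- cbind(lab[rep(5, 170), ], gpd = exp(-1), survey_year = 2009)
  co <- rbind(rows, lo)
  fit <- fit_maihda_model(co, d, "lognormal", "null",
                          mcmc = maihda_mcmc(iter = 800, burn_in = 300, seed = 4,
                                             fix_sigma_u2 = 0.5,
                                             fix_sigma_e2 = 1))
  u <- colMeans(fit$u)[1:4]
  expect_true(all(diff(u) >= 0))   # same raw deviation, increasing n
})

test_that("fits are reproducible from the seed and flag degenerate designs", {
  co <- simulate_cohort(108 * 20, years = 2009, seed = 14)
  mc <- maihda_mcmc(iter = 300, burn_in = 100, seed = 9)
  f1 <- suppressWarnings(fit_maihda_model(co, nhis_design(), "binomial", "null", mcmc = mc))
  f2 <- suppressWarnings(fit_maihda_model(co, nhis_design(), "binomial", "null", mcmc = mc))
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$sigma_u2, f2$sigma_u2)

  one <- co[co$stratum == 1, ]
  expect_error(fit_maihda_model(one, nhis_design(), "binomial", "null"),
               "single populated stratum")
})

test_that("credible intervals for a contrast attain near-nominal coverage", {
  # 40 replicate simulate-and-fit experiments, women contrast, linear family
  hits <- 0L
  for (r in 1:40) {
    co <- simulate_cohort(2160, outcomes = "gpd", years = 2009, seed = 1000 + r)
    fit <- suppressWarnings(
      fit_maihda_model(co, nhis_design(), "lognormal", "main",
                       mcmc = maihda_mcmc(chains = 1L, iter = 700,
                                          burn_in = 300, seed = r)))
    ci <- quantile(fit$beta[, "sexWomen"], c(0.025, 0.975))
    if (ci[1] <= -0.98 && -0.98 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 34L)  # >= 85% of 40
})

test_that("posterior summaries agree with an independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  co <- simulate_cohort(108 * 60, outcomes = "gpd", years = 2009, seed = 61)
  fit <- fit_maihda_model(co, nhis_design(), "lognormal", "main",
                          mcmc = maihda_mcmc(iter = 1200, burn_in = 400, seed = 5))
  co$logy <- log(co$gpd)
  lf <- lme4::lmer(logy ~ sex + race_ethnicity + age_group + education +
                     (1 | stratum), data = co)
  ml_beta <- lme4::fixef(lf)[["sexWomen"]]
  ml_su <- unname(lme4::VarCorr(lf)$stratum[1])
  expect_lt(abs(mean(fit$beta[, "sexWomen"]) - ml_beta), 0.05)
  expect_lt(abs(mean(fit$sigma_u2) - ml_su), 0.04)
})
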
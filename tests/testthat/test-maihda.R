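test_that("VPC arithmetic matches hand calculation and handles edge cases", {
  expect_equal(round(compute_vpc(0.67, pi^2 / 3), 3), 0.169)
  expect_equal(round(compute_vpc(0.41, 2.98), 3), 0.121)
  expect_equal(compute_vpc(0, 5), 0)
  expect_equal(compute_vpc(c(0.5, 1), c(0.5, 1)), c(0.5, 0.5))
  expect_error(compute_vpc(0, 0), "zero")
  expect_error(compute_vpc(-1, 2), "non-negative")
})

test_that("PCV arithmetic matches hand calculation", {
  expect_equal(round(compute_pcv(0.67, 0.05), 3), 0.925)
  expect_equal(round(compute_pcv(0.41, 0.04), 3), 0.902)
  expect_equal(compute_pcv(0.3, 0.3), 0)
  expect_error(compute_pcv(0, 0.1), "positive")
})

test_that("a single-draw logistic prediction reproduces hand inverse-logit", {
  d <- nhis_design()
  cols <- main_cols(d)
  beta <- matrix(0, 1, length(cols), dimnames = list(NULL, cols))
  beta[, "(Intercept)"] <- 1.21
  beta[, "sexWomen"] <- -0.55
  u <- matrix(0, 1, 108)
  fit <- fake_fit(d, beta, u)
  pr <- predict_strata(fit)
  # women at reference levels elsewhere: logit^-1(1.21 - 0.55) = 0.659
  f_ref <- which(d$strata$label == "F, 21-24, White, low")
  expect_equal(pr$total[f_ref] / 100, 1 / (1 + exp(-0.66)), tolerance = 1e-6)
  expect_equal(round(pr$total[f_ref], 1), 65.9)
  # with u = 0, total equals additive everywhere and nothing is significant
  expect_equal(pr$total, pr$additive)
  expect_true(all(pr$interaction == 0))
  expect_false(any(pr$significant))
  expect_true(all(pr$total > 0 & pr$total < 100))
})

test_that("raising the intercept raises every stratum's prediction", {
  d <- toy_design()
  cols <- main_cols(d)
  mk <- function(b0) {
    beta <- matrix(0, 1, length(cols), dimnames = list(NULL, cols))
    beta[, "(Intercept)"] <- b0
    beta[, "sexWomen"] <- -0.4
    predict_strata(fake_fit(d, beta, matrix(0.2, 1, 6)))$total
  }
  expect_true(all(mk(1.0) > mk(0.5)))
})

test_that("total = additive + interaction exactly, per draw and per summary", {
  co <- simulate_cohort(108 * 40, years = 2009, seed = 12)
  fit <- suppressWarnings(
    fit_maihda_model(co, nhis_design(), "binomial", "main",
                     mcmc = maihda_mcmc(iter = 500, burn_in = 200, seed = 2)))
  pr <- predict_strata(fit, keep_draws = TRUE)
  dr <- attr(pr, "draws")
  inter <- dr$total - dr$additive
  expect_equal(pr$total, pr$additive + pr$interaction, tolerance = 1e-12)
  expect_equal(unname(rowMeans(inter)), pr$interaction, tolerance = 1e-12)
  # intervals come from per-draw differences, not interval arithmetic
  expect_equal(unname(apply(inter, 1, quantile, 0.025)),
               pr$interaction_lower, tolerance = 1e-12)
})

test_that("interaction decomposition flags and reproduces printed examples", {
  # draws constructed so summaries land on known values
  tot <- matrix(c(85.4, 38.6), 2, 50)
  add <- matrix(c(81.5, 52.9), 2, 50)
  dec <- decompose_interaction(tot, add)
  expect_equal(dec$interaction, c(3.9, -14.3), tolerance = 1e-9)
  expect_equal(dec$additive + dec$interaction, dec$total)

  same <- decompose_interaction(tot, tot)
  expect_true(all(same$interaction == 0))
  expect_false(any(same$significant))
  expect_error(decompose_interaction(tot, add[, 1:10]), "misaligned")
})

test_that("lognormal back-transformation has the closed form and MC limit", {
  expect_equal(backtransform_lognormal(0, 0), 1)
  expect_equal(backtransform_lognormal(1, 2), exp(2))
  # Monte-Carlo oracle: E exp(N(eta, s2)) at 10^6 draws within 1%
  set.seed(3)
  eta <- 0.7; s2 <- 1.3
  mc <- mean(exp(rnorm(1e6, eta, sqrt(s2))))
  expect_lt(abs(mc / backtransform_lognormal(eta, s2) - 1), 0.01)
  # sigma_e2 -> 0 reduces to exp(eta)
  expect_equal(backtransform_lognormal(c(0.2, 1.5), 1e-12),
               exp(c(0.2, 1.5)), tolerance = 1e-6)
  expect_error(backtransform_lognormal(1, -0.1), "non-negative")
  # smearing hook replaces the lognormal factor
  expect_equal(backtransform_lognormal(1, 2, smear = 1.5), exp(1) * 1.5)
})

test_that("VPC is invariant to a constant stratum shift with intercept offset", {
  base <- default_truth_gpd("null")
  shifted <- generating_truth("lognormal",
                              c("(Intercept)" = unname(base$fixed_effects) - 0.3),
                              stratum_sd = base$stratum_sd,
                              interaction_offsets = rep(0.3, 108),
                              residual_sd = base$residual_sd)
  a <- simulate_cohort(5400, outcomes = "gpd", years = 2009,
                       truth_gpd = base, seed = 6)
  b <- simulate_cohort(5400, outcomes = "gpd", years = 2009,
                       truth_gpd = shifted, seed = 6)
  expect_equal(a$gpd, b$gpd)   # identical linear predictors, identical streams
})

test_that("the full wrapper returns a coherent analysis object", {
  co <- simulate_cohort(108 * 30, years = 2008:2010, seed = 18)
  m <- suppressWarnings(
    maihda(drinker ~ sex + race_ethnicity + age_group + education,
           data = co, family = "binomial", design = nhis_design(),
           mcmc = maihda_mcmc(iter = 400, burn_in = 200, seed = 3)))
  expect_s3_class(m, "maihda")
  expect_equal(m$ref_year, 2009)
  expect_equal(nrow(m$predictions), 108L)
  expect_true(m$variance$vpc_null >= 0 && m$variance$vpc_null <= 1)
  expect_equal(m$variance$mode, "draws")
  # methods run
  expect_output(print(m), "Intersectional MAIHDA")
  expect_true(all(c("mean", "lower", "upper") %in% colnames(coef(m))))
  expect_identical(predict(m), m$predictions)
  s <- summary(m)
  expect_output(print(s), "Fixed effects")
  sims <- simulate(m, nsim = 2, seed = 5, n = 500)
  expect_length(sims, 2L)
  expect_equal(nrow(sims[[1]]), 500L)
  # formula/axis mismatch is caught
  expect_error(maihda(drinker ~ sex + education, co, "binomial",
                      design = nhis_design()), "do not match")
})

test_that("additive-only truth yields few significant interactions", {
  truth <- generating_truth("binomial", default_truth_status()$fixed_effects,
                            stratum_sd = 0)
  co <- simulate_cohort(108 * 300, truth_status = truth, outcomes = "status",
                        years = 2009, seed = 44)
  fit <- suppressWarnings(
    fit_maihda_model(co, nhis_design(), "binomial", "main",
                     mcmc = maihda_mcmc(iter = 1200, burn_in = 500, seed = 5)))
  pr <- predict_strata(fit)
  # false-positive-like rate, far below the ~1/3 seen with real interactions
  expect_lt(mean(pr$significant), 0.15)
})

test_that("known interaction offsets are recovered by the stratum effects", {
  set.seed(9)
  off <- rnorm(108, 0, 0.3)
  off <- off - mean(off)
  truth <- generating_truth("lognormal", default_truth_gpd()$fixed_effects,
                            stratum_sd = 0, interaction_offsets = off,
                            residual_sd = sqrt(2.98))
  co <- simulate_cohort(108 * 300, outcomes = "gpd", years = 2009,
                        truth_gpd = truth, seed = 27)
  fit <- suppressWarnings(
    fit_maihda_model(co, nhis_design(), "lognormal", "main",
                     mcmc = maihda_mcmc(iter = 1000, burn_in = 400, seed = 8)))
  expect_gt(cor(colMeans(fit$u), off), 0.8)
})

test_that("variance summary supports the plug-in posterior-means mode", {
  co <- simulate_cohort(108 * 25, years = 2009, seed = 2)
  mc <- maihda_mcmc(iter = 400, burn_in = 200, seed = 2)
  fn <- suppressWarnings(fit_maihda_model(co, nhis_design(), "binomial", "null", mcmc = mc))
  fm <- suppressWarnings(fit_maihda_model(co, nhis_design(), "binomial", "main", mcmc = mc))
  vd <- variance_summary(fn, fm, mode = "draws")
  vm <- variance_summary(fn, fm, mode = "means")
  expect_equal(vm$pcv,
               compute_pcv(mean(fn$sigma_u2), mean(fm$sigma_u2)))
  expect_equal(vd$mode, "draws")
  expect_equal(vm$mode, "means")
  # the two summarization modes agree closely on well-mixed fits
  expect_lt(abs(vd$vpc_null - vm$vpc_null), 0.02)
})
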
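test_that("identical seed and configuration reproduce the cohort exactly", {
  a <- simulate_cohort(2000, seed = 123)
  b <- simulate_cohort(2000, seed = 123)
  expect_identical(a, b)
  fa <- tempfile(); fb <- tempfile()
  write_cohort(a, fa); write_cohort(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  expect_false(identical(a$drinker, simulate_cohort(2000, seed = 124)$drinker))
})

test_that("an intercept-only status model at zero gives a half drinker share", {
  truth <- generating_truth("binomial", c("(Intercept)" = 0), stratum_sd = 0)
  co <- simulate_cohort(10000, truth_status = truth, outcomes = "status",
                        years = 2009, seed = 5)
  # binomial 3-sigma band around 0.5 at n = 10,000
  expect_lt(abs(mean(co$drinker) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("equal allocation populates every stratum near-evenly", {
  co <- simulate_cohort(108 * 7 + 5, seed = 2)
  tab <- tabulate(co$stratum, 108)
  expect_true(all(tab %in% c(7L, 8L)))
  expect_error(simulate_cohort(50, seed = 1), "infeasible")
  expect_error(simulate_cohort(500, allocation = "weights", seed = 1),
               "weight per stratum")
})

test_that("generated consumption respects the cap and drinker-only support", {
  co <- simulate_cohort(20000, seed = 31)
  expect_true(all(is.na(co$gpd[co$drinker == 0])))
  expect_true(all(co$gpd[co$drinker == 1] <= 200))
  expect_true(all(co$gpd[co$drinker == 1] > 0))
})

test_that("unknown coefficient names in the truth are rejected", {
  bad <- generating_truth("binomial",
                          c("(Intercept)" = 0, "sexNonbinary" = 1))
  expect_error(simulate_cohort(500, truth_status = bad, seed = 1),
               "unknown design-matrix column")
})

test_that("empirical stratum log-odds track the generating effects with unit slope", {
  truth <- default_truth_status("null")
  co <- simulate_cohort(108 * 800, truth_status = truth, outcomes = "status",
                        years = 2009, seed = 77)
  u <- cohort_truth(co)$status$u
  p_j <- tapply(co$drinker, co$stratum, mean)
  elo <- qlogis(pmin(pmax(p_j, 1e-4), 1 - 1e-4))
  sl <- coef(lm(elo ~ u))[2]
  expect_gt(sl, 0.9)
  expect_lt(sl, 1.1)
})

test_that("a single-level logistic fit recovers the women contrast", {
  co <- simulate_cohort(1e5, years = 2009, u_mode = "orthogonal", seed = 19)
  co$sex <- factor(co$sex, levels = c("Men", "Women"))
  co$race_ethnicity <- factor(co$race_ethnicity,
                              levels = nhis_design()$axes$race_ethnicity$levels)
  co$age_group <- factor(co$age_group, levels = c("21-24", "25-59", "60+"))
  co$education <- factor(co$education, levels = c("low", "medium", "high"))
  # independent oracle: off-the-shelf single-level glm on the generated table
  fit <- glm(drinker ~ sex + race_ethnicity + age_group + education,
             data = co, family = binomial())
  expect_lt(abs(unname(coef(fit)["sexWomen"]) - (-0.55)), 0.05)
})

test_that("interaction offsets shift the generating linear predictor", {
  off <- c(2, rep(0, 5))
  d <- toy_design()
  truth0 <- generating_truth("binomial", c("(Intercept)" = 0), stratum_sd = 0)
  truth1 <- generating_truth("binomial", c("(Intercept)" = 0), stratum_sd = 0,
                             interaction_offsets = off)
  co <- simulate_cohort(6000, design = d, truth_status = truth0,
                        outcomes = "status", years = 2009, seed = 3)
  co1 <- simulate_cohort(6000, design = d, truth_status = truth1,
                         outcomes = "status", years = 2009, seed = 3)
  p0 <- mean(co$drinker[co$stratum == 1])
  p1 <- mean(co1$drinker[co1$stratum == 1])
  expect_gt(p1, p0 + 0.2) # logit shift of +2 raises 0.5 to ~0.88
  expect_error(simulate_cohort(600, design = d, outcomes = "status", seed = 1,
                               truth_status = generating_truth(
                                 "binomial", c("(Intercept)" = 0),
                                 interaction_offsets = c(1, 2))),
               "length")
})

test_that("orthogonal u draws have exact variance and no main-effect leakage", {
  co <- simulate_cohort(216, u_mode = "orthogonal", seed = 8)
  tr <- cohort_truth(co)
  u <- tr$status$u
  expect_equal(mean(u^2), tr$status$truth$stratum_sd^2, tolerance = 1e-10)
  Xs <- maihda:::.stratum_main_matrix(nhis_design())
  expect_lt(max(abs(crossprod(Xs, u))), 1e-8)
})

test_that("missingness injection blanks fields at the requested rates", {
  co <- simulate_cohort(10000, years = 2009, seed = 4)
  expect_identical(inject_missingness(co, c(education = 0), seed = 1), co)
  all_gone <- inject_missingness(co, c(education = 1), seed = 1)
  expect_true(all(is.na(all_gone$education)))
  some <- inject_missingness(co, c(education = 0.043), seed = 9)
  n_miss <- sum(is.na(some$education))
  expect_lt(abs(n_miss - 430), 3 * sqrt(10000 * 0.043 * 0.957))
  # other fields untouched
  expect_identical(some$drinker, co$drinker)
  expect_error(inject_missingness(co, c(education = 1.2)), "\\[0, 1\\]")
})
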
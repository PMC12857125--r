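#' Intersectional MAIHDA analysis
#'
#' Fits the full MAIHDA pair — a null (intercept-only) and a main-effects
#' two-level Bayesian random-intercept model — for one outcome, then derives
#' the variance partition (VPC of the null and main models, and the
#' proportional change in variance, PCV), and per-stratum predictions at a
#' reference survey year decomposed into additive-only and interaction
#' components on the outcome scale.
#'
#' The formula names the outcome and the social-category axes, e.g.
#' `drinker ~ sex + race_ethnicity + age_group + education`. For
#' `family = "binomial"` the outcome is a 0/1 drinker indicator and
#' predictions are percentages of current drinkers; for
#' `family = "lognormal"` the outcome is positive grams/day, capped at `cap`,
#' modelled on the natural-log scale, and predictions are back-transformed
#' mean grams/day via the log-normal mean retransformation
#' `exp(eta + sigma_e2/2)` applied per posterior draw.
#'
#' Per-stratum total predictions incorporate the stratum random effect
#' (`eta_add + u_j`); additive-only predictions use the fixed effects alone;
#' the interaction component is their per-draw difference, so
#' `total = additive + interaction` holds exactly for every draw and for the
#' posterior-mean summaries. An interaction is flagged significant when its
#' 95% credible interval excludes zero.
#'
#' @param formula Outcome ~ axis terms (axes must match `design`, or a design
#'   is built from the data's observed levels).
#' @param data Cohort data frame.
#' @param family `"binomial"` or `"lognormal"`.
#' @param design Optional [strata_design()]; defaults to axes built from the
#'   data with levels in sorted order (pass [nhis_design()] for the canonical
#'   108-stratum system).
#' @param year_col Survey-year column (year dummies enter the main model when
#'   several years are present).
#' @param ref_year Year at which stratum predictions are evaluated (default
#'   2009 when present in the data, else the earliest year).
#' @param cap Grams/day cap applied before the log transform (lognormal only).
#' @param mcmc A [maihda_mcmc()] configuration used for both fits.
#' @return An object of class `maihda`: components `null_fit`, `main_fit`
#'   (class `maihda_fit`), `variance` (class `maihda_variance`),
#'   `predictions` (class `maihda_predictions`), `design`, `family`,
#'   `ref_year`.
#' @examples
#' cohort <- simulate_cohort(3240, years = 2009, seed = 7)
#' m <- maihda(drinker ~ sex + race_ethnicity + age_group + education,
#'             data = cohort, family = "binomial", design = nhis_design(),
#'             mcmc = maihda_mcmc(iter = 400, burn_in = 200))
#' m$variance$vpc_null
#' @export
maihda <- function(formula, data, family = c("binomial", "lognormal"),
                   design = NULL, year_col = "survey_year", ref_year = NULL,
                   cap = 200, mcmc = maihda_mcmc()) {
  family <- match.arg(family)
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  outcome <- all.vars(formula[[2L]])
  axes_names <- all.vars(formula[[3L]])
  if (!length(axes_names)) stop("formula must name at least one category axis")
  missing_cols <- setdiff(c(outcome, axes_names), names(data))
  if (length(missing_cols))
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))

  if (is.null(design)) {
    design <- strata_design(lapply(axes_names, function(a)
      category_axis(a, sort(unique(stats::na.omit(data[[a]]))))))
  } else {
    if (!setequal(axes_names, names(design$axes)))
      stop("formula axes do not match the design's axes")
  }

  if (family == "lognormal" && !is.null(cap)) {
    data[[outcome]] <- cap_gpd(data[[outcome]], cap = cap)
  }
  if (is.null(ref_year) && year_col %in% names(data)) {
    yrs <- unique(data[[year_col]])
    ref_year <- if (2009 %in% yrs) 2009 else min(yrs)
  }

  null_fit <- fit_maihda_model(data, design, family, "null", outcome = outcome,
                               year_col = year_col, mcmc = mcmc)
  main_fit <- fit_maihda_model(data, design, family, "main", outcome = outcome,
                               ref_year = ref_year, year_col = year_col,
                               mcmc = mcmc)
  variance <- variance_summary(null_fit, main_fit)
  predictions <- predict_strata(main_fit, ref_year = ref_year)

  structure(list(null_fit = null_fit, main_fit = main_fit,
                 variance = variance, predictions = predictions,
                 design = design, family = family, outcome = outcome,
                 ref_year = ref_year, call = match.call()),
            class = "maihda")
}

## ---- variance partition ----------------------------------------------

#' Variance partition coefficient
#'
#' Share of total latent outcome variance lying between strata:
#' `sigma_u2 / (sigma_u2 + sigma_e2)`. Operates per posterior draw when
#' given draw vectors (recycled against each other); for logistic models the
#' individual-level variance is the standard-logistic constant `pi^2/3`
#' (3.29, latent-response formulation).
#'
#' @param sigma_u2 Stratum-level variance (scalar or draws).
#' @param sigma_e2 Individual-level variance (scalar or draws).
#' @return Proportion(s) in `[0, 1]`.
#' @examples
#' compute_vpc(0.67, pi^2 / 3) # about 0.169
#' @export
compute_vpc <- function(sigma_u2, sigma_e2) {
  if (any(sigma_u2 < 0) || any(sigma_e2 < 0)) stop("variances must be non-negative")
  if (any(sigma_u2 + sigma_e2 == 0)) stop("total variance is zero")
  sigma_u2 / (sigma_u2 + sigma_e2)
}

#' Proportional change in variance
#'
#' Proportion of the null model's between-stratum variance absorbed by
#' adding main effects: `(sigma_u2_null - sigma_u2_main) / sigma_u2_null`.
#' Vectorized over paired draws.
#'
#' @param sigma_u2_null,sigma_u2_main Stratum-level variances (scalars or
#'   aligned draw vectors).
#' @return Proportion(s); near 1 when main effects explain almost all
#'   between-stratum variance.
#' @examples
#' compute_pcv(0.67, 0.05) # about 0.925
#' @export
compute_pcv <- function(sigma_u2_null, sigma_u2_main) {
  if (any(sigma_u2_null <= 0)) stop("null stratum variance must be positive")
  (sigma_u2_null - sigma_u2_main) / sigma_u2_null
}

#' Summarize the variance partition of a null/main model pair
#'
#' Computes the VPC of each model and the PCV. By default (`mode =
#' "draws"`) VPC and PCV are posterior means of the per-draw functionals
#' (PCV pairs null and main draws index-wise); `mode = "means"` plugs
#' posterior-mean variances into the formulas instead. The mode is recorded
#' in the result.
#'
#' @param null_fit,main_fit `maihda_fit` objects for the same outcome.
#' @param mode `"draws"` or `"means"`.
#' @return An object of class `maihda_variance`: posterior summaries of the
#'   stratum variances, `sigma_e2`, `vpc_null`, `vpc_main`, `pcv` (all
#'   proportions) and the summarization `mode`.
#' @export
variance_summary <- function(null_fit, main_fit, mode = c("draws", "means")) {
  mode <- match.arg(mode)
  stopifnot(inherits(null_fit, "maihda_fit"), inherits(main_fit, "maihda_fit"))
  if (mode == "draws" && length(null_fit$sigma_u2) != length(main_fit$sigma_u2))
    mode <- "means"
  su_n <- null_fit$sigma_u2; su_m <- main_fit$sigma_u2
  se_n <- null_fit$sigma_e2; se_m <- main_fit$sigma_e2
  if (mode == "draws") {
    vpc_null <- mean(compute_vpc(su_n, se_n))
    vpc_main <- mean(compute_vpc(su_m, se_m))
    pcv <- mean(compute_pcv(su_n, su_m))
  } else {
    vpc_null <- compute_vpc(mean(su_n), mean(se_n))
    vpc_main <- compute_vpc(mean(su_m), mean(se_m))
    pcv <- compute_pcv(mean(su_n), mean(su_m))
  }
  qi <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  structure(list(
    sigma_u2_null = c(mean = mean(su_n), lower = qi(su_n)[1L], upper = qi(su_n)[2L]),
    sigma_u2_main = c(mean = mean(su_m), lower = qi(su_m)[1L], upper = qi(su_m)[2L]),
    sigma_e2_null = mean(se_n), sigma_e2_main = mean(se_m),
    vpc_null = vpc_null, vpc_main = vpc_main, pcv = pcv, mode = mode,
    family = null_fit$family
  ), class = "maihda_variance")
}

#' @export
print.maihda_variance <- function(x, ...) {
  pct <- function(p) sprintf("%.1f%%", 100 * p)
  cat("Variance partition (", x$family, " family, mode = ", x$mode, ")\n", sep = "")
  cat("  stratum variance: null ", format(x$sigma_u2_null[["mean"]], digits = 3),
      ", main ", format(x$sigma_u2_main[["mean"]], digits = 3), "\n", sep = "")
  cat("  individual variance: ", format(x$sigma_e2_null, digits = 3), "\n", sep = "")
  cat("  VPC: null ", pct(x$vpc_null), ", main ", pct(x$vpc_main),
      "; PCV ", pct(x$pcv), "\n", sep = "")
  invisible(x)
}

## ---- stratum predictions ----------------------------------------------

#' Per-stratum predictions decomposed into additive and interaction parts
#'
#' Evaluates, for every stratum and every posterior draw of the main-effects
#' fit, the additive linear predictor (intercept + category contrasts +
#' reference-year effect) and the total predictor (additive + stratum random
#' effect), maps both to the outcome scale (inverse logit as a percentage
#' for the binomial family; log-normal mean back-transformation for the
#' lognormal family), and summarizes across draws: posterior means and
#' 2.5/97.5 percentile intervals. The interaction component is the per-draw
#' difference, so its interval reflects the joint posterior, not interval
#' arithmetic.
#'
#' @param fit A main-effects `maihda_fit`.
#' @param ref_year Survey year for prediction (must be a year of the fit;
#'   default the fit's reference year).
#' @param keep_draws Attach the per-draw matrices as attribute `"draws"`.
#' @return A data frame of class `maihda_predictions` with one row per
#'   stratum: `stratum`, `label`, `total`, `total_lower`, `total_upper`,
#'   `additive`, `additive_lower`, `additive_upper`, `interaction`,
#'   `interaction_lower`, `interaction_upper`, `significant`.
#' @export
predict_strata <- function(fit, ref_year = NULL, keep_draws = FALSE) {
  stopifnot(inherits(fit, "maihda_fit"))
  if (fit$model != "main")
    stop("stratum decomposition requires a main-effects fit")
  design <- fit$design
  Xs <- .stratum_main_matrix(design)
  X <- matrix(0, nrow(Xs), length(fit$columns),
              dimnames = list(NULL, fit$columns))
  common <- intersect(colnames(Xs), fit$columns)
  X[, common] <- Xs[, common]
  if (is.null(ref_year)) ref_year <- fit$ref_year
  if (fit$year_dummies && !is.null(ref_year) && length(fit$years)) {
    if (!ref_year %in% fit$years)
      stop("reference year ", ref_year, " was not in the fitted data")
    yc <- paste0("year", ref_year)
    if (yc %in% fit$columns) X[, yc] <- 1
  }

  eta_add <- X %*% t(fit$beta)           # strata x draws
  eta_tot <- eta_add + t(fit$u)
  if (fit$family == "binomial") {
    tot <- 100 * stats::plogis(eta_tot)
    add <- 100 * stats::plogis(eta_add)
  } else {
    se2 <- matrix(fit$sigma_e2, nrow(eta_add), ncol(eta_add), byrow = TRUE)
    tot <- backtransform_lognormal(eta_tot, se2)
    add <- backtransform_lognormal(eta_add, se2)
  }
  dec <- decompose_interaction(tot, add)
  out <- data.frame(stratum = design$strata$index, label = design$strata$label,
                    dec, stringsAsFactors = FALSE)
  class(out) <- c("maihda_predictions", "data.frame")
  attr(out, "family") <- fit$family
  attr(out, "ref_year") <- ref_year
  if (keep_draws) attr(out, "draws") <- list(total = tot, additive = add)
  out
}

#' Isolate interaction effects by per-draw subtraction
#'
#' Given aligned per-draw outcome-scale matrices (strata x draws) of total
#' and additive-only predictions, computes the interaction component
#' `total - additive` per draw and summarizes all three with posterior means
#' and 95% credible intervals. Positive interactions mean higher outcomes
#' than the additive combination of the stratum's social positions would
#' predict. `significant` flags intervals excluding zero.
#'
#' @param total,additive Numeric matrices (or vectors) of identical shape.
#' @return Data frame with summary columns for total, additive and
#'   interaction plus a logical `significant`.
#' @export
decompose_interaction <- function(total, additive) {
  total <- rbind(total); additive <- rbind(additive)
  if (!all(dim(total) == dim(additive)))
    stop("total and additive draws are misaligned")
  interaction <- total - additive
  sm <- function(m) {
    q <- apply(m, 1L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
    data.frame(est = rowMeans(m), lower = q[1L, ], upper = q[2L, ])
  }
  st <- sm(total); sa <- sm(additive); si <- sm(interaction)
  data.frame(total = st$est, total_lower = st$lower, total_upper = st$upper,
             additive = sa$est, additive_lower = sa$lower, additive_upper = sa$upper,
             interaction = si$est, interaction_lower = si$lower,
             interaction_upper = si$upper,
             significant = si$lower > 0 | si$upper < 0)
}

#' Log-normal mean back-transformation
#'
#' Maps log-scale linear predictors to expected outcomes on the original
#' scale using the log-normal mean, `exp(eta + sigma_e2 / 2)`, applied per
#' posterior draw; draws are then summarized downstream. As
#' `sigma_e2 -> 0` this reduces to `exp(eta)`. A nonparametric smearing
#' variant is available by passing a `smear` factor (the mean of
#' exponentiated residuals), which replaces the `exp(sigma_e2 / 2)` factor.
#'
#' @param eta Linear predictor draws (vector or matrix).
#' @param sigma_e2 Residual variance draws, recycled against `eta`.
#' @param smear Optional smearing factor(s) overriding the log-normal factor.
#' @return Strictly positive values, same shape as `eta`.
#' @examples
#' backtransform_lognormal(1, 2) # exp(2)
#' @export
backtransform_lognormal <- function(eta, sigma_e2, smear = NULL) {
  if (any(sigma_e2 < 0)) stop("sigma_e2 must be non-negative")
  if (!is.null(smear)) return(exp(eta) * smear)
  exp(eta + sigma_e2 / 2)
}

#' Run the full two-outcome MAIHDA analysis
#'
#' Convenience wrapper fitting the drinking-status (binomial) and
#' consumption (lognormal, drinkers only) analyses on one cohort, plus their
#' between-outcome correlation.
#'
#' @param data Cohort data frame with `drinker` and `gpd` columns.
#' @param design A [strata_design()].
#' @param ref_year Prediction year (default 2009 when present).
#' @param mcmc A [maihda_mcmc()] configuration.
#' @param cap Grams/day cap.
#' @return List with `status` and `gpd` (class `maihda`) and `correlation`
#'   (class `maihda_correlation`).
#' @export
run_maihda <- function(data, design = nhis_design(), ref_year = NULL,
                       mcmc = maihda_mcmc(), cap = 200) {
  fm <- stats::reformulate(names(design$axes))
  status <- maihda(stats::update(fm, drinker ~ .), data, "binomial",
                   design = design, ref_year = ref_year, mcmc = mcmc)
  drinkers <- apply_exclusions(data, list(rule_nondrinker(), rule_missing_gpd(),
                                          rule_inconsistent_gpd()))$kept
  gpd <- maihda(stats::update(fm, gpd ~ .), drinkers, "lognormal",
                design = design, ref_year = ref_year, cap = cap, mcmc = mcmc)
  list(status = status, gpd = gpd,
       correlation = correlate_outcomes(status$predictions, gpd$predictions))
}
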
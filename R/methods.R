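#' @export
print.maihda <- function(x, ...) {
  cat("Intersectional MAIHDA analysis (", x$family, " family)\n", sep = "")
  cat("  outcome: ", x$outcome, "; n = ", x$main_fit$n, " individuals in ",
      length(x$main_fit$populated), "/", x$main_fit$n_strata, " strata\n", sep = "")
  if (!is.null(x$ref_year)) cat("  predictions at year ", x$ref_year, "\n", sep = "")
  print(x$variance)
  nsig <- sum(x$predictions$significant)
  cat("  significant interactions: ", nsig, "/", nrow(x$predictions),
      " strata\n", sep = "")
  conv <- x$null_fit$converged && x$main_fit$converged
  if (!conv) cat("  NOTE: convergence flag raised on at least one fit\n")
  invisible(x)
}

#' @export
summary.maihda <- function(object, k = 5L, ...) {
  out <- list(
    family = object$family,
    variance = object$variance,
    coef = coef(object),
    highest = rank_strata(object$predictions, k, "highest"),
    lowest = rank_strata(object$predictions, k, "lowest"),
    positive = rank_strata(object$predictions, k, "positive_interaction"),
    negative = rank_strata(object$predictions, k, "negative_interaction"),
    n_significant = sum(object$predictions$significant),
    n_strata = nrow(object$predictions),
    converged = object$null_fit$converged && object$main_fit$converged
  )
  class(out) <- "summary.maihda"
  out
}

#' @export
print.summary.maihda <- function(x, ...) {
  cat("MAIHDA summary (", x$family, " family)\n\n", sep = "")
  print(x$variance)
  cat("\nFixed effects (posterior mean, 95% CI):\n")
  print(round(x$coef, 3))
  cat("\nHighest strata:\n"); print(x$highest, row.names = FALSE)
  cat("\nLowest strata:\n"); print(x$lowest, row.names = FALSE)
  cat("\nLargest significant positive interactions:\n")
  print(x$positive, row.names = FALSE)
  cat("\nLargest significant negative interactions:\n")
  print(x$negative, row.names = FALSE)
  cat("\nSignificant interactions: ", x$n_significant, "/", x$n_strata, "\n", sep = "")
  invisible(x)
}

#' Posterior fixed-effect summaries
#'
#' @param object A `maihda` object.
#' @param model `"main"` (default) or `"null"`.
#' @param ... Unused.
#' @return Matrix with posterior `mean`, `lower`, `upper` (95% credible
#'   bounds) per fixed-effect column of the chosen model.
#' @export
coef.maihda <- function(object, model = c("main", "null"), ...) {
  model <- match.arg(model)
  fit <- if (model == "main") object$main_fit else object$null_fit
  q <- apply(fit$beta, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  cbind(mean = colMeans(fit$beta), lower = q[1L, ], upper = q[2L, ])
}

#' Stratum predictions from a fitted MAIHDA analysis
#'
#' Returns the per-stratum decomposition table, recomputed at another
#' reference year on request.
#'
#' @param object A `maihda` object.
#' @param ref_year Optional alternative prediction year.
#' @param ... Unused.
#' @return A `maihda_predictions` data frame.
#' @export
predict.maihda <- function(object, ref_year = NULL, ...) {
  if (is.null(ref_year) || identical(ref_year, object$ref_year))
    return(object$predictions)
  predict_strata(object$main_fit, ref_year = ref_year)
}

#' Caterpillar plot of stratum predictions
#'
#' Plots each stratum's total (filled point, dark) and additive-only (open
#' point, light) prediction with 95% credible-interval bars, ordered by the
#' additive prediction and coloured by the first level of the `group` axis
#' (sex by default) when available. Layout is deterministic.
#'
#' @param x A `maihda` object (or pass a `maihda_predictions` table to
#'   [caterpillar_plot()]).
#' @param group Axis name used for colouring (default `"sex"` when present).
#' @param ... Passed to [caterpillar_plot()].
#' @export
plot.maihda <- function(x, group = NULL, ...) {
  caterpillar_plot(x$predictions, design = x$design, group = group,
                   family = x$family, ...)
}

#' Simulate cohorts from a fitted MAIHDA analysis
#'
#' Posterior-predictive style generation: draws new synthetic cohorts using
#' the posterior means of the fitted main-effects model as generating truth.
#'
#' @param object A `maihda` object.
#' @param nsim Number of cohorts.
#' @param seed Integer seed (incremented per cohort).
#' @param n Individuals per cohort (default: the fitted sample size).
#' @param ... Unused.
#' @return A list of `nsim` cohort data frames.
#' @export
simulate.maihda <- function(object, nsim = 1L, seed = 1L, n = NULL, ...) {
  fit <- object$main_fit
  if (is.null(n)) n <- fit$n
  fe <- colMeans(fit$beta)
  fe <- fe[!grepl("^year", names(fe))]
  truth <- generating_truth(
    family = if (object$family == "binomial") "binomial" else "lognormal",
    fixed_effects = fe,
    stratum_sd = sqrt(mean(fit$sigma_u2)),
    residual_sd = if (object$family == "lognormal") sqrt(mean(fit$sigma_e2)) else NULL
  )
  lapply(seq_len(nsim), function(i) {
    if (object$family == "binomial")
      simulate_cohort(n, design = object$design, truth_status = truth,
                      outcomes = "status", years = object$ref_year %||% 2009,
                      seed = seed + i - 1L)
    else
      simulate_cohort(n, design = object$design, truth_gpd = truth,
                      outcomes = "gpd", years = object$ref_year %||% 2009,
                      seed = seed + i - 1L)
  })
}
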
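#' Generating truth for synthetic cohorts
#'
#' Bundles the parameters of the two-level generating model used by
#' [simulate_cohort()]: fixed-effect coefficients on the link scale (named by
#' design-matrix column, e.g. `sexWomen`), the stratum random-effect standard
#' deviation, optional explicit per-stratum interaction offsets added to the
#' linear predictor, and (for the log-normal family) the individual-level
#' residual standard deviation.
#'
#' @param family `"binomial"` (logit link, binary outcome) or `"lognormal"`
#'   (identity link on the log scale, outcome exponentiated).
#' @param fixed_effects Named numeric vector; must include `"(Intercept)"`.
#'   Names must be design-matrix columns of the target design (unknown names
#'   are an error at generation time). Year-dummy effects (names like
#'   `"year2005"`) default to zero when absent.
#' @param stratum_sd Standard deviation of the stratum random intercepts
#'   (`sqrt` of the stratum-level variance).
#' @param interaction_offsets Optional numeric vector, one per stratum of the
#'   design, added to the linear predictor (explicit multiplicative effects).
#' @param residual_sd Individual-level standard deviation on the log scale
#'   (log-normal family only).
#' @return An object of class `generating_truth`.
#' @seealso [default_truth_status()], [default_truth_gpd()]
#' @export
generating_truth <- function(family = c("binomial", "lognormal"),
                             fixed_effects,
                             stratum_sd = 0,
                             interaction_offsets = NULL,
                             residual_sd = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(fixed_effects), !is.null(names(fixed_effects)))
  if (!"(Intercept)" %in% names(fixed_effects))
    stop("fixed_effects must include '(Intercept)'")
  if (stratum_sd < 0) stop("stratum_sd must be >= 0")
  if (family == "lognormal") {
    if (is.null(residual_sd)) stop("lognormal truth requires residual_sd")
    if (residual_sd < 0) stop("residual_sd must be >= 0")
  }
  structure(list(family = family, fixed_effects = fixed_effects,
                 stratum_sd = stratum_sd,
                 interaction_offsets = interaction_offsets,
                 residual_sd = residual_sd),
            class = "generating_truth")
}

#' Default generating truths for the NHIS-like cohort
#'
#' Coefficients and variance components mirroring the magnitudes estimated
#' for US adult drinking, on the [nhis_design()] axes. The `"main"` status
#' truth places the intercept at 1.21 log-odds for the reference stratum
#' (young White men with low education) with a women contrast of -0.55 and a
#' stratum-level variance of 0.05; the `"null"` truth collapses all fixed
#' effects into an intercept of 0.26 with stratum variance 0.67. The
#' consumption (grams/day) truths are on the natural-log scale with residual
#' variance 2.98: the `"main"` model has intercept 1.62 and women contrast
#' -0.98 with stratum variance 0.04; the `"null"` model intercept 0.57 with
#' stratum variance 0.41. Year effects default to zero.
#'
#' @param model `"main"` (category contrasts) or `"null"` (intercept only).
#' @return A [generating_truth()].
#' @examples
#' default_truth_status()$fixed_effects[["sexWomen"]] # -0.55
#' @export
default_truth_status <- function(model = c("main", "null")) {
  model <- match.arg(model)
  if (model == "null") {
    return(generating_truth("binomial",
                            c("(Intercept)" = 0.26), stratum_sd = sqrt(0.67)))
  }
  generating_truth(
    "binomial",
    c("(Intercept)" = 1.21,
      "sexWomen" = -0.55,
      "race_ethnicityHispanic" = -0.77,
      "race_ethnicityBlack" = -1.06,
      "race_ethnicityAsian" = -0.22,
      "race_ethnicityMixed-race" = -0.80,
      "race_ethnicityAI/AN" = -0.55,
      "age_group25-59" = -0.38,
      "age_group60+" = -1.30,
      "educationmedium" = 0.57,
      "educationhigh" = 0.82),
    stratum_sd = sqrt(0.05)
  )
}

#' @rdname default_truth_status
#' @export
default_truth_gpd <- function(model = c("main", "null")) {
  model <- match.arg(model)
  if (model == "null") {
    return(generating_truth("lognormal",
                            c("(Intercept)" = 0.57), stratum_sd = sqrt(0.41),
                            residual_sd = sqrt(2.98)))
  }
  generating_truth(
    "lognormal",
    c("(Intercept)" = 1.62,
      "sexWomen" = -0.98,
      "race_ethnicityHispanic" = -0.46,
      "race_ethnicityBlack" = -0.64,
      "race_ethnicityAsian" = -0.18,
      "race_ethnicityMixed-race" = -0.11,
      "race_ethnicityAI/AN" = -0.41,
      "age_group25-59" = -0.41,
      "age_group60+" = -0.66,
      "educationmedium" = 0.04,
      "educationhigh" = 0.18),
    stratum_sd = sqrt(0.04),
    residual_sd = sqrt(2.98)
  )
}
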
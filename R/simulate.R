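#' Simulate an NHIS-like synthetic cohort
#'
#' Draws individual records with the statistical structure the MAIHDA
#' analysis assumes: drinker status from a two-level logistic model
#' (`logit p = x'beta + year effect + u_j + offset_j`, `u_j ~ N(0, sd_u^2)`)
#' and, for drinkers, grams of pure alcohol per day from a log-normal model
#' with its own stratum effects, capped at 200 g. The generator is the
#' model's inverse, so fits on its output support known-truth
#' parameter-recovery experiments.
#'
#' Random-number use is split into separate streams for allocation
#' (stratum, year, age), stratum effects, and outcomes, so changing one
#' component does not perturb the draws of the others. Identical `seed` and
#' configuration give byte-identical cohorts.
#'
#' `u_mode = "iid"` draws stratum effects independently; `"orthogonal"`
#' additionally residualizes the realized effects against the stratum-level
#' main-effects design and rescales them so their realized mean square equals
#' the nominal stratum variance exactly. The orthogonal mode is intended for
#' parameter-recovery experiments, where the stratum deviations represent
#' pure interaction structure and the realized stratum variance should equal
#' its nominal value rather than a finite-sample draw of it.
#'
#' @param n Number of individuals (>= number of strata under equal allocation).
#' @param design A [strata_design()]; default [nhis_design()] (108 strata).
#' @param truth_status [generating_truth()] for the binary drinker outcome.
#' @param truth_gpd [generating_truth()] for log-scale consumption.
#' @param outcomes `"both"` (status for everyone, gpd for drinkers),
#'   `"status"` only, or `"gpd"` (everyone a drinker with a consumption draw).
#' @param allocation `"equal"` (near-equal counts per stratum), `"weights"`
#'   (multinomial with `weights`), or `"skewed"` (a heavy-imbalance preset
#'   emulating real survey strata ranging over four orders of magnitude).
#' @param weights Optional positive weights, one per stratum.
#' @param years Inclusive vector of survey years sampled uniformly.
#' @param u_mode `"iid"` or `"orthogonal"` (see Details).
#' @param gpd_cap Cap applied to emitted grams/day.
#' @param seed Integer seed controlling all streams.
#' @return Data frame with columns `sex`, `race_ethnicity`, `age_group`,
#'   `education`, `age_years`, `survey_year`, `stratum`, `drinker`, `gpd`,
#'   with the realized generating quantities attached as attribute `"truth"`
#'   (see [cohort_truth()]).
#' @examples
#' cohort <- simulate_cohort(1080, seed = 1)
#' table(cohort$drinker)
#' @export
simulate_cohort <- function(n,
                            design = nhis_design(),
                            truth_status = default_truth_status(),
                            truth_gpd = default_truth_gpd(),
                            outcomes = c("both", "status", "gpd"),
                            allocation = c("equal", "weights", "skewed"),
                            weights = NULL,
                            years = 2000:2018,
                            u_mode = c("iid", "orthogonal"),
                            gpd_cap = 200,
                            seed = 1L) {
  outcomes <- match.arg(outcomes)
  allocation <- match.arg(allocation)
  u_mode <- match.arg(u_mode)
  stopifnot(inherits(design, "strata_design"), n >= 1)
  J <- nrow(design$strata)

  set.seed(as.integer(seed))
  subseeds <- sample.int(.Machine$integer.max - 1L, 3L)

  ## stream 1: allocation of strata, years, ages -------------------------
  set.seed(subseeds[1L])
  stratum <- switch(allocation,
    equal = {
      if (n < J) stop("equal allocation infeasible: n < number of strata")
      base <- rep(seq_len(J), n %/% J)
      extra <- seq_len(n %% J)
      sort(c(base, extra))
    },
    weights = {
      if (is.null(weights) || length(weights) != J || any(weights <= 0))
        stop("allocation = 'weights' needs one positive weight per stratum")
      sort(sample.int(J, n, replace = TRUE, prob = weights / sum(weights)))
    },
    skewed = {
      w <- exp(1.75 * stats::qnorm(stats::ppoints(J)))
      sort(sample.int(J, n, replace = TRUE, prob = w / sum(w)))
    }
  )
  survey_year <- sample(rep_len(years, max(n, length(years))), n, replace = TRUE)
  labels <- stratum_labels(stratum, design)
  age_years <- if ("age_group" %in% names(labels)) {
    lo <- c("21-24" = 21L, "25-59" = 25L, "60+" = 60L)[labels$age_group]
    hi <- c("21-24" = 24L, "25-59" = 59L, "60+" = 84L)[labels$age_group]
    ifelse(is.na(lo), NA_integer_, lo + as.integer(floor(stats::runif(n) * (hi - lo + 1L))))
  } else rep(NA_integer_, n)

  cohort <- data.frame(labels, age_years = age_years, survey_year = survey_year,
                       stratum = stratum, stringsAsFactors = FALSE)

  ## stream 2: stratum random effects ------------------------------------
  set.seed(subseeds[2L])
  u_status <- .draw_stratum_effects(design, truth_status$stratum_sd, u_mode)
  u_gpd <- .draw_stratum_effects(design, truth_gpd$stratum_sd, u_mode)

  ## stream 3: outcomes ---------------------------------------------------
  set.seed(subseeds[3L])
  drinker <- rep(NA_integer_, n)
  gpd <- rep(NA_real_, n)
  ref_year <- min(years)
  if (outcomes %in% c("both", "status")) {
    eta <- .truth_linear_predictor(cohort, design, truth_status, ref_year) +
      u_status[stratum]
    drinker <- as.integer(stats::runif(n) < stats::plogis(eta))
  }
  if (outcomes == "gpd") drinker <- rep(1L, n)
  if (outcomes %in% c("both", "gpd")) {
    who <- which(drinker == 1L)
    if (length(who)) {
      eta_g <- .truth_linear_predictor(cohort[who, , drop = FALSE], design,
                                       truth_gpd, ref_year) +
        u_gpd[stratum[who]]
      gpd[who] <- cap_gpd(exp(stats::rnorm(length(who), eta_g, truth_gpd$residual_sd)),
                          cap = gpd_cap)
    }
  }
  cohort$drinker <- drinker
  cohort$gpd <- gpd

  attr(cohort, "truth") <- list(
    status = list(u = u_status, truth = truth_status),
    gpd = list(u = u_gpd, truth = truth_gpd),
    seed = seed, ref_year = ref_year, u_mode = u_mode
  )
  cohort
}

# realized stratum effects, optionally orthogonalized against the
# stratum-level main-effects design and rescaled to exact variance
.draw_stratum_effects <- function(design, sd_u, u_mode) {
  J <- nrow(design$strata)
  if (sd_u == 0) return(numeric(J))
  u <- stats::rnorm(J, 0, sd_u)
  if (u_mode == "orthogonal") {
    Xs <- .stratum_main_matrix(design)
    if (ncol(Xs) >= J) stop("orthogonal u_mode needs more strata than main-effect columns")
    u <- stats::lm.fit(Xs, u)$residuals
    ms <- sqrt(mean(u^2))
    if (ms == 0) stop("degenerate stratum-effect draw")
    u <- u * sd_u / ms
  }
  u
}

# linear predictor from truth fixed effects at record level
.truth_linear_predictor <- function(data, design, truth, ref_year) {
  dm <- .build_design_matrix(data, design, model = "main",
                             year_dummies = TRUE, ref_year = ref_year)
  fe <- truth$fixed_effects
  unknown <- setdiff(names(fe), colnames(dm$X))
  if (length(unknown))
    stop("truth names unknown design-matrix column(s): ",
         paste(unknown, collapse = ", "))
  beta <- numeric(ncol(dm$X))
  names(beta) <- colnames(dm$X)
  beta[names(fe)] <- fe
  eta <- drop(dm$X %*% beta)
  if (!is.null(truth$interaction_offsets)) {
    off <- truth$interaction_offsets
    if (length(off) != nrow(design$strata))
      stop("interaction_offsets length must equal the stratum count")
    eta <- eta + off[dm$stratum]
  }
  eta
}

#' Retrieve the generating truth attached to a synthetic cohort
#'
#' @param cohort A data frame returned by [simulate_cohort()].
#' @return List with components `status` and `gpd` (each holding the realized
#'   stratum effects `u` and the [generating_truth()]), the seed, the
#'   reference year and the u-draw mode.
#' @export
cohort_truth <- function(cohort) {
  tr <- attr(cohort, "truth")
  if (is.null(tr)) stop("cohort carries no generating truth")
  tr
}

#' Blank fields at random to emulate survey missingness
#'
#' Each targeted field is independently set to `NA` with its own rate, using
#' a dedicated random stream so the rest of the cohort is untouched.
#'
#' @param data Cohort data frame.
#' @param rates Named numeric vector/list of per-field missingness
#'   probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return The data frame with fields blanked.
#' @examples
#' d <- data.frame(education = rep("low", 10))
#' sum(is.na(inject_missingness(d, c(education = 0.5), seed = 1)$education))
#' @export
inject_missingness <- function(data, rates, seed = 1L) {
  rates <- unlist(rates)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  bad <- setdiff(names(rates), names(data))
  if (length(bad)) stop("unknown field(s): ", paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  for (f in names(rates)) {
    hit <- stats::runif(nrow(data)) < rates[[f]]
    data[[f]][hit] <- NA
  }
  data
}
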
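#' MCMC configuration for MAIHDA fits
#'
#' Diffuse-prior defaults: independent Normal(0, `prior_sd_fixed`^2) priors
#' on fixed effects and a weakly-informative inverse-gamma prior on variance
#' components (a uniform prior on the standard deviation is selectable).
#' Convergence is flagged (never silently ignored) when the split-chain
#' statistic exceeds `rhat_limit` or any effective sample size falls below
#' `ess_limit`.
#'
#' @param chains Number of chains (>= 1).
#' @param iter Total iterations per chain.
#' @param burn_in Discarded initial iterations (`< iter`).
#' @param thin Keep every `thin`-th post-burn-in draw (>= 1).
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param prior_sd_fixed Prior standard deviation of fixed effects.
#' @param variance_prior `"invgamma"` (shape `ig_shape`, rate `ig_rate`) or
#'   `"uniform_sd"` (uniform on the standard deviation over
#'   `(0, uniform_sd_max)`).
#' @param ig_shape,ig_rate Inverse-gamma hyperparameters.
#' @param uniform_sd_max Upper bound for the uniform-on-SD prior.
#' @param fix_sigma_u2,fix_sigma_e2 Optional known variance values held fixed
#'   during sampling (used for validation against closed-form shrinkage).
#' @param rhat_limit,ess_limit Convergence-flag thresholds.
#' @return A list of class `maihda_mcmc`.
#' @export
maihda_mcmc <- function(chains = 2L, iter = 5000L, burn_in = 2500L, thin = 1L,
                        seed = 1L, prior_sd_fixed = 1000,
                        variance_prior = c("invgamma", "uniform_sd"),
                        ig_shape = 0.001, ig_rate = 0.001,
                        uniform_sd_max = 100,
                        fix_sigma_u2 = NULL, fix_sigma_e2 = NULL,
                        rhat_limit = 1.05, ess_limit = 200) {
  variance_prior <- match.arg(variance_prior)
  stopifnot(chains >= 1L, iter >= 2L, burn_in >= 0L, burn_in < iter, thin >= 1L)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), prior_sd_fixed = prior_sd_fixed,
                 variance_prior = variance_prior, ig_shape = ig_shape,
                 ig_rate = ig_rate, uniform_sd_max = uniform_sd_max,
                 fix_sigma_u2 = fix_sigma_u2, fix_sigma_e2 = fix_sigma_e2,
                 rhat_limit = rhat_limit, ess_limit = ess_limit),
            class = "maihda_mcmc")
}

#' Build the MAIHDA design matrix
#'
#' Constructs the individual-level fixed-effects indicator matrix and stratum
#' index vector for a null (intercept-only) or main-effects specification.
#' Reference levels contribute no column; the main specification has one
#' contrast column per non-reference level of each axis, named
#' `<axis><level>`, plus optional survey-year dummies named `year<year>`
#' (reference year absorbed into the intercept).
#'
#' @param data Data frame with one column per design axis (and the year
#'   column if `year_dummies`).
#' @param design A [strata_design()].
#' @param model `"null"` or `"main"`.
#' @param year_dummies Include survey-year dummy columns?
#' @param ref_year Year absorbed into the intercept; default the earliest
#'   year present.
#' @param year_col Name of the survey-year column.
#' @return List with `X` (numeric matrix), `stratum` (integer vector),
#'   `years` (years present) and `ref_year`.
#' @examples
#' d <- nhis_design()
#' cohort <- simulate_cohort(216, design = d, years = 2009, seed = 1)
#' dm <- maihda_design_matrix(cohort, d, model = "main")
#' ncol(dm$X) # intercept + 1 + 5 + 2 + 2 contrasts
#' @export
maihda_design_matrix <- function(data, design, model = c("main", "null"),
                                 year_dummies = (model == "main"),
                                 ref_year = NULL, year_col = "survey_year") {
  model <- match.arg(model)
  .build_design_matrix(data, design, model, year_dummies, ref_year, year_col)
}

.build_design_matrix <- function(data, design, model = "main",
                                 year_dummies = FALSE, ref_year = NULL,
                                 year_col = "survey_year") {
  stopifnot(inherits(design, "strata_design"))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  n <- nrow(data)
  stratum <- stratum_index(data, design)
  cols <- list("(Intercept)" = rep(1, n))
  if (model == "main") {
    for (a in design$axes) {
      li <- match(as.character(data[[a$name]]), a$levels)
      for (lev in setdiff(a$levels, a$reference))
        cols[[paste0(a$name, lev)]] <- as.numeric(li == match(lev, a$levels))
    }
  }
  years <- integer(0)
  if (year_dummies) {
    if (!year_col %in% names(data))
      stop("year dummies requested but column '", year_col, "' is absent")
    yr <- data[[year_col]]
    years <- sort(unique(yr))
    if (is.null(ref_year)) ref_year <- min(years)
    if (!ref_year %in% years)
      stop("reference year ", ref_year, " not present in the data")
    for (y in setdiff(years, ref_year))
      cols[[paste0("year", y)]] <- as.numeric(yr == y)
  } else if (year_col %in% names(data)) {
    years <- sort(unique(data[[year_col]]))
    if (is.null(ref_year)) ref_year <- if (length(years)) min(years) else NA
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, stratum = stratum, years = years, ref_year = ref_year)
}

# stratum-level main-effects matrix (one row per stratum, no year columns)
.stratum_main_matrix <- function(design) {
  .build_design_matrix(design$strata, design, model = "main",
                       year_dummies = FALSE, year_col = "..none..")$X
}

# collapse individual rows into (stratum x year) cells; rows within a cell
# share an identical design-matrix row, so sufficient statistics per cell
# (count, outcome sum, outcome sum of squares) are all the samplers need
.collapse_cells <- function(X, stratum, year_code, y) {
  key <- (stratum - 1) * (max(year_code) + 1) + year_code
  f <- as.integer(factor(key))
  L <- max(f)
  n_c <- tabulate(f, nbins = L)
  s_c <- drop(rowsum(y, f))
  ss_c <- drop(rowsum(y * y, f))
  first <- which(!duplicated(f))
  first <- first[order(f[first])]
  list(X = X[first, , drop = FALSE], j = stratum[first],
       n = n_c, s = s_c, ss = ss_c)
}

#' Fit one two-level MAIHDA model by MCMC
#'
#' Fits a Bayesian random-intercept model with individuals nested in
#' intersectional strata: logistic (`family = "binomial"`) for a binary
#' outcome, or linear on the natural-log scale (`family = "lognormal"`) for a
#' positive skewed outcome (logged internally). Estimation is by Gibbs
#' sampling on data collapsed to stratum-by-year cells — conjugate
#' normal/inverse-gamma updates for the linear family and Polya-Gamma
#' augmentation for the logistic family — with the diffuse priors of
#' [maihda_mcmc()]. The logistic family has no free individual-level
#' variance; the latent-response constant `pi^2/3` (3.29) is stored in its
#' place.
#'
#' @param data Cohort data frame (axis columns, year column, outcome).
#' @param design A [strata_design()].
#' @param family `"binomial"` or `"lognormal"`.
#' @param model `"null"` (intercept only) or `"main"` (category contrasts,
#'   plus year dummies by default).
#' @param outcome Outcome column name; defaults to `"drinker"` (binomial) or
#'   `"gpd"` (lognormal).
#' @param year_dummies Include survey-year fixed effects (default: main
#'   model only, and only when several years are present).
#' @param ref_year Reference year absorbed into the intercept.
#' @param year_col Survey-year column name.
#' @param mcmc A [maihda_mcmc()] configuration.
#' @return An object of class `maihda_fit`: post-burn-in thinned draws
#'   (`beta`, `u`, `sigma_u2`, `sigma_e2`, with `chain` indices), the design,
#'   per-parameter split-chain convergence diagnostics (`rhat`, `ess`), and a
#'   `converged` flag.
#' @examples
#' cohort <- simulate_cohort(2160, years = 2009, seed = 42)
#' fit <- fit_maihda_model(cohort, nhis_design(), "binomial", "null",
#'                         mcmc = maihda_mcmc(iter = 300, burn_in = 150))
#' fit$converged
#' @export
fit_maihda_model <- function(data, design, family = c("binomial", "lognormal"),
                             model = c("main", "null"), outcome = NULL,
                             year_dummies = NULL, ref_year = NULL,
                             year_col = "survey_year",
                             mcmc = maihda_mcmc()) {
  family <- match.arg(family)
  model <- match.arg(model)
  stopifnot(inherits(mcmc, "maihda_mcmc"))
  if (is.null(outcome)) outcome <- if (family == "binomial") "drinker" else "gpd"
  if (!outcome %in% names(data)) stop("outcome column '", outcome, "' not found")

  y_raw <- data[[outcome]]
  keep <- !is.na(y_raw)
  data <- data[keep, , drop = FALSE]
  y_raw <- y_raw[keep]
  if (!nrow(data)) stop("no usable outcome values")
  y <- if (family == "binomial") {
    if (!all(y_raw %in% c(0, 1))) stop("binomial outcome must be 0/1")
    as.numeric(y_raw)
  } else {
    log_gpd(y_raw)
  }

  if (is.null(year_dummies)) {
    yrs <- if (year_col %in% names(data)) unique(data[[year_col]]) else integer(0)
    year_dummies <- model == "main" && length(yrs) > 1L
  }
  dm <- .build_design_matrix(data, design, model, year_dummies, ref_year, year_col)
  year_code <- if (year_col %in% names(data) && length(dm$years))
    match(data[[year_col]], dm$years) else rep(1L, nrow(data))
  cells <- .collapse_cells(dm$X, dm$stratum, year_code, y)

  J <- nrow(design$strata)
  jp <- sort(unique(cells$j))
  if (length(jp) < 2L)
    stop("stratum variance is unidentified with a single populated stratum")

  sampler <- if (family == "binomial") .gibbs_logistic else .gibbs_linear
  chains <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    chains[[ch]] <- sampler(cells, J, mcmc, chain_seed = mcmc$seed + ch - 1L)
  }

  keep_idx <- seq(mcmc$burn_in + 1L, mcmc$iter, by = mcmc$thin)
  draws <- .stack_chains(chains, keep_idx, colnames(dm$X), J)
  diag <- .mcmc_diagnostics(chains, keep_idx, colnames(dm$X))
  converged <- all(is.finite(diag$rhat)) &&
    max(diag$rhat) <= mcmc$rhat_limit && min(diag$ess) >= mcmc$ess_limit
  if (!converged)
    warning("convergence flag raised: max rhat = ",
            format(max(diag$rhat), digits = 4), ", min ess = ",
            format(min(diag$ess), digits = 4), call. = FALSE)

  structure(list(family = family, model = model, outcome = outcome,
                 design = design, columns = colnames(dm$X),
                 years = dm$years, ref_year = dm$ref_year,
                 year_dummies = year_dummies,
                 beta = draws$beta, u = draws$u,
                 sigma_u2 = draws$sigma_u2, sigma_e2 = draws$sigma_e2,
                 chain = draws$chain,
                 n = nrow(data), n_strata = J, populated = jp,
                 diagnostics = diag, converged = converged,
                 mcmc = mcmc),
            class = "maihda_fit")
}

#' @export
print.maihda_fit <- function(x, ...) {
  cat("MAIHDA ", x$family, " ", x$model, "-model fit\n", sep = "")
  cat("  n = ", x$n, " individuals, ", length(x$populated), "/", x$n_strata,
      " strata populated\n", sep = "")
  cat("  ", length(x$sigma_u2), " retained draws (", x$mcmc$chains,
      " chains)\n", sep = "")
  cat("  stratum variance: ", format(mean(x$sigma_u2), digits = 3),
      "  individual variance: ", format(mean(x$sigma_e2), digits = 3), "\n",
      sep = "")
  cat("  converged: ", x$converged, " (max rhat ",
      format(max(x$diagnostics$rhat), digits = 4), ")\n", sep = "")
  invisible(x)
}

.stack_chains <- function(chains, keep_idx, beta_names, J) {
  beta <- do.call(rbind, lapply(chains, function(ch) ch$beta[keep_idx, , drop = FALSE]))
  u <- do.call(rbind, lapply(chains, function(ch) ch$u[keep_idx, , drop = FALSE]))
  sigma_u2 <- unlist(lapply(chains, function(ch) ch$sigma_u2[keep_idx]))
  sigma_e2 <- unlist(lapply(chains, function(ch) ch$sigma_e2[keep_idx]))
  colnames(beta) <- beta_names
  colnames(u) <- paste0("u", seq_len(J))
  chain <- rep(seq_along(chains), each = length(keep_idx))
  list(beta = beta, u = u, sigma_u2 = sigma_u2, sigma_e2 = sigma_e2, chain = chain)
}

## ---- samplers ---------------------------------------------------------

.variance_draw <- function(ssq, k, ctrl) {
  # posterior draw of a variance given k effects with sum of squares ssq
  if (ctrl$variance_prior == "invgamma") {
    1 / stats::rgamma(1L, shape = ctrl$ig_shape + k / 2,
                      rate = ctrl$ig_rate + ssq / 2)
  } else {
    # sigma ~ Uniform(0, A)  =>  1/sigma^2 ~ Gamma((k-1)/2, ssq/2) truncated
    shape <- (k - 1) / 2
    if (shape <= 0) return(stats::runif(1L, 0, ctrl$uniform_sd_max)^2)
    lo <- stats::pgamma(1 / ctrl$uniform_sd_max^2, shape, rate = ssq / 2)
    p <- stats::runif(1L, lo, 1)
    1 / stats::qgamma(min(p, 1 - 1e-12), shape, rate = ssq / 2)
  }
}

.gibbs_linear <- function(cells, J, ctrl, chain_seed) {
  set.seed(chain_seed)
  X <- cells$X; p <- ncol(X)
  n_c <- cells$n; s_c <- cells$s; ss_c <- cells$ss; j_c <- cells$j
  ybar <- s_c / n_c
  N <- sum(n_c)
  jp <- sort(unique(j_c))
  jfac <- match(j_c, jp)
  n_j <- drop(rowsum(n_c, jfac))
  XtNX <- crossprod(X * sqrt(n_c))
  prior_prec <- diag(1 / ctrl$prior_sd_fixed^2, p)
  tau2 <- ctrl$prior_sd_fixed^2
  sinfo <- .stratum_level_info(cells, jfac)

  beta <- numeric(p); beta[1L] <- sum(s_c) / N
  u <- numeric(J)
  sigma_e2 <- ctrl$fix_sigma_e2 %||%
    max((sum(ss_c) - sum(s_c)^2 / N) / N, 1e-6)
  sigma_u2 <- ctrl$fix_sigma_u2 %||% 0.1

  out_beta <- matrix(NA_real_, ctrl$iter, p)
  out_u <- matrix(NA_real_, ctrl$iter, J)
  out_su <- out_se <- numeric(ctrl$iter)

  for (it in seq_len(ctrl$iter)) {
    eta_x <- drop(X %*% beta)
    # stratum effects
    rs <- drop(rowsum(n_c * (ybar - eta_x), jfac))
    prec <- n_j / sigma_e2 + 1 / sigma_u2
    u[jp] <- rs / sigma_e2 / prec + stats::rnorm(length(jp)) / sqrt(prec)
    if (length(jp) < J)
      u[-jp] <- stats::rnorm(J - length(jp), 0, sqrt(sigma_u2))
    # fixed effects
    A <- XtNX / sigma_e2 + prior_prec
    b <- drop(crossprod(X, n_c * (ybar - u[j_c]))) / sigma_e2
    R <- chol(A)
    beta <- backsolve(R, backsolve(R, b, transpose = TRUE) + stats::rnorm(p))
    # recentering (parameter expansion) to decouple beta from mean(u)
    re <- .asis_recenter(beta, u[jp], sinfo, sigma_u2, tau2)
    beta <- re$beta; u[jp] <- re$u_p
    # variances
    eta <- drop(X %*% beta) + u[j_c]
    if (is.null(ctrl$fix_sigma_e2)) {
      ssr <- sum(ss_c) - 2 * sum(s_c * eta) + sum(n_c * eta^2)
      sigma_e2 <- max(.variance_draw(ssr, N, ctrl), 1e-10)
    }
    if (is.null(ctrl$fix_sigma_u2)) {
      sigma_u2 <- max(.variance_draw(sum(u[jp]^2), length(jp), ctrl), 1e-10)
    }
    out_beta[it, ] <- beta
    out_u[it, ] <- u
    out_su[it] <- sigma_u2
    out_se[it] <- sigma_e2
  }
  list(beta = out_beta, u = out_u, sigma_u2 = out_su, sigma_e2 = out_se)
}

.gibbs_logistic <- function(cells, J, ctrl, chain_seed) {
  set.seed(chain_seed)
  X <- cells$X; p <- ncol(X)
  n_c <- cells$n; s_c <- cells$s; j_c <- cells$j
  kappa <- s_c - n_c / 2
  jp <- sort(unique(j_c))
  jfac <- match(j_c, jp)
  prior_prec <- diag(1 / ctrl$prior_sd_fixed^2, p)
  tau2 <- ctrl$prior_sd_fixed^2
  sinfo <- .stratum_level_info(cells, jfac)
  sigma_e2_const <- pi^2 / 3

  pbar <- min(max(sum(s_c) / sum(n_c), 1e-3), 1 - 1e-3)
  beta <- numeric(p); beta[1L] <- stats::qlogis(pbar)
  u <- numeric(J)
  sigma_u2 <- ctrl$fix_sigma_u2 %||% 0.1

  out_beta <- matrix(NA_real_, ctrl$iter, p)
  out_u <- matrix(NA_real_, ctrl$iter, J)
  out_su <- numeric(ctrl$iter)

  for (it in seq_len(ctrl$iter)) {
    eta_x <- drop(X %*% beta)
    eta <- eta_x + u[j_c]
    omega <- rpg(n_c, eta)
    # stratum effects
    so <- drop(rowsum(omega, jfac))
    rs <- drop(rowsum(kappa - omega * eta_x, jfac))
    prec <- so + 1 / sigma_u2
    u[jp] <- rs / prec + stats::rnorm(length(jp)) / sqrt(prec)
    if (length(jp) < J)
      u[-jp] <- stats::rnorm(J - length(jp), 0, sqrt(sigma_u2))
    # fixed effects
    A <- crossprod(X * sqrt(omega)) + prior_prec
    b <- drop(crossprod(X, kappa - omega * u[j_c]))
    R <- chol(A)
    beta <- backsolve(R, backsolve(R, b, transpose = TRUE) + stats::rnorm(p))
    # recentering (parameter expansion) to decouple beta from mean(u)
    re <- .asis_recenter(beta, u[jp], sinfo, sigma_u2, tau2)
    beta <- re$beta; u[jp] <- re$u_p
    # stratum variance
    if (is.null(ctrl$fix_sigma_u2)) {
      sigma_u2 <- max(.variance_draw(sum(u[jp]^2), length(jp), ctrl), 1e-10)
    }
    out_beta[it, ] <- beta
    out_u[it, ] <- u
    out_su[it] <- sigma_u2
  }
  list(beta = out_beta, u = out_u, sigma_u2 = out_su,
       sigma_e2 = rep(sigma_e2_const, ctrl$iter))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stratum-determined design columns and the stratum-level covariate matrix
# over populated strata, used by the parameter-expansion recentering step.
.stratum_level_info <- function(cells, jfac) {
  p <- ncol(cells$X)
  const <- vapply(seq_len(p), function(k) {
    a <- tapply(cells$X[, k], jfac, min)
    b <- tapply(cells$X[, k], jfac, max)
    all(a == b)
  }, logical(1L))
  Sp <- which(const)
  first <- which(!duplicated(jfac))
  first <- first[order(jfac[first])]
  Xs <- cells$X[first, Sp, drop = FALSE]
  list(cols = Sp, Xs = Xs, XtXs = crossprod(cells$X[first, Sp, drop = FALSE]))
}

# Location/contrast parameter expansion (ASIS): the likelihood is invariant
# to shifting stratum-level fixed effects by c while subtracting Xs %*% c
# from the stratum effects; drawing c from its conditional under the priors
# and applying the shift breaks the intercept-vs-mean(u) random walk that
# otherwise cripples mixing in these models.
.asis_recenter <- function(beta, u_p, info, sigma_u2, tau2) {
  pS <- length(info$cols)
  A <- info$XtXs / sigma_u2 + diag(1 / tau2, pS)
  b <- drop(crossprod(info$Xs, u_p)) / sigma_u2 - beta[info$cols] / tau2
  R <- chol(A)
  cc <- backsolve(R, backsolve(R, b, transpose = TRUE) + stats::rnorm(pS))
  beta[info$cols] <- beta[info$cols] + cc
  u_p <- u_p - drop(info$Xs %*% cc)
  list(beta = beta, u_p = u_p)
}

## ---- diagnostics ------------------------------------------------------

# split each chain's post-burn-in draws in half and compute the usual
# between/within variance ratio (split-chain R-hat) and effective sample
# size from combined-chain autocorrelations (initial positive sequence)
.mcmc_diagnostics <- function(chains, keep_idx, beta_names) {
  params <- c(beta_names, "sigma_u2", "sigma_e2")
  get <- function(ch, pn) {
    if (pn == "sigma_u2") ch$sigma_u2[keep_idx]
    else if (pn == "sigma_e2") ch$sigma_e2[keep_idx]
    else ch$beta[keep_idx, match(pn, beta_names)]
  }
  rhat <- ess <- numeric(length(params))
  for (k in seq_along(params)) {
    series <- lapply(chains, get, pn = params[k])
    halves <- unlist(lapply(series, function(x) {
      h <- length(x) %/% 2L
      list(x[seq_len(h)], x[h + seq_len(h)])
    }), recursive = FALSE)
    rhat[k] <- .split_rhat(halves)
    ess[k] <- .ess(halves)
  }
  data.frame(parameter = params, rhat = rhat, ess = ess,
             stringsAsFactors = FALSE)
}

.split_rhat <- function(halves) {
  n <- length(halves[[1L]])
  if (n < 2L) return(NA_real_)
  vars <- vapply(halves, stats::var, numeric(1L))
  means <- vapply(halves, mean, numeric(1L))
  W <- mean(vars)
  if (W < 1e-300) return(1)
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.ess <- function(halves) {
  n <- length(halves[[1L]]); m <- length(halves)
  vars <- vapply(halves, stats::var, numeric(1L))
  W <- mean(vars)
  if (W < 1e-300) return(m * n)
  B <- n * stats::var(vapply(halves, mean, numeric(1L)))
  var_hat <- (n - 1) / n * W + B / n
  max_lag <- min(n - 2L, 500L)
  ac <- vapply(halves, function(x) {
    stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1L] *
      stats::var(x)
  }, numeric(max_lag))
  rho <- 1 - (W - rowMeans(ac)) / var_hat
  # Geyer initial positive sequence on paired sums
  s <- 0; t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2L
  }
  max(m * n / (1 + 2 * s), 1)
}

## ---- closed-form shrinkage oracle -------------------------------------

#' Closed-form shrunken stratum means (BLUP oracle)
#'
#' For a linear null model with known variance components, the posterior
#' mean stratum deviation has the closed form
#' `u_j = lambda_j * (ybar_j - mu)`, with shrinkage factor
#' `lambda_j = sigma_u2 / (sigma_u2 + sigma_e2 / n_j)` and `mu` the
#' precision-weighted grand mean of stratum means. Small strata are pulled
#' strongly toward the grand mean; empty strata shrink fully (`u_j = 0`).
#' This is an independent oracle for validating the MCMC sampler, not a
#' fitting routine.
#'
#' @param y Numeric outcome vector.
#' @param stratum Integer stratum index per observation.
#' @param sigma_u2,sigma_e2 Known variance components.
#' @param n_strata Total number of strata (default: highest index seen).
#' @param mu Optional grand mean; default the precision-weighted grand mean.
#' @return List with `mu`, and per-stratum `n`, `lambda`, `u`.
#' @examples
#' blup_shrinkage(c(1, 2, 3, 4), c(1, 1, 2, 2), sigma_u2 = 1, sigma_e2 = 4)
#' @export
blup_shrinkage <- function(y, stratum, sigma_u2, sigma_e2,
                           n_strata = max(stratum), mu = NULL) {
  stopifnot(sigma_u2 >= 0, sigma_e2 > 0)
  n_j <- tabulate(stratum, nbins = n_strata)
  sum_j <- numeric(n_strata)
  sum_j[sort(unique(stratum))] <- drop(rowsum(y, stratum))
  ybar <- ifelse(n_j > 0, sum_j / pmax(n_j, 1L), NA_real_)
  lambda <- ifelse(n_j > 0, sigma_u2 / (sigma_u2 + sigma_e2 / pmax(n_j, 1L)), 0)
  if (is.null(mu)) {
    w <- ifelse(n_j > 0, 1 / (sigma_u2 + sigma_e2 / pmax(n_j, 1L)), 0)
    mu <- sum(w * ifelse(n_j > 0, ybar, 0)) / sum(w)
  }
  u <- ifelse(n_j > 0, lambda * (ybar - mu), 0)
  list(mu = mu, n = n_j, lambda = lambda, u = u)
}
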
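# small design and record builders shared across tests

toy_design <- function() {
  strata_design(list(
    category_axis("sex", c("Men", "Women"), short_codes = c(Men = "M", Women = "F")),
    category_axis("education", c("low", "medium", "high"))
  ))
}

# one record per stratum x year, fully deterministic
records_grid <- function(design, years = 2009) {
  g <- merge(design$strata[, names(design$axes), drop = FALSE],
             data.frame(survey_year = years))
  g[order(stratum_index(g, design), g$survey_year), , drop = FALSE]
}

# a fake main-effects fit with handpicked draws, for prediction arithmetic
fake_fit <- function(design, beta, u, sigma_e2 = pi^2 / 3,
                     family = "binomial") {
  ndraw <- nrow(beta)
  structure(list(
    family = family, model = "main", outcome = "y", design = design,
    columns = colnames(beta), years = integer(0), ref_year = NULL,
    year_dummies = FALSE, beta = beta, u = u,
    sigma_u2 = rep(stats::var(as.vector(u)), ndraw),
    sigma_e2 = rep_len(sigma_e2, ndraw), chain = rep(1L, ndraw),
    n = 0L, n_strata = nrow(design$strata),
    populated = seq_len(nrow(design$strata)),
    diagnostics = data.frame(parameter = "none", rhat = 1, ess = Inf),
    converged = TRUE, mcmc = maihda_mcmc(iter = 2, burn_in = 0)
  ), class = "maihda_fit")
}

main_cols <- function(design) colnames(maihda:::.stratum_main_matrix(design))
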
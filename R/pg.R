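#' Polya-Gamma random variates
#'
#' Draws from the Polya-Gamma distribution PG(b, z), the augmentation
#' variable that renders Bayesian logistic regression conditionally Gaussian
#' (Polson-Scott-Windle data augmentation). For binomial cell counts `b` the
#' draw is exact-in-distribution via the infinite gamma convolution
#' `PG(b, z) = (1/(2*pi^2)) * sum_k g_k / ((k - 1/2)^2 + z^2/(4*pi^2))`,
#' `g_k ~ Gamma(b, 1)`, truncated at 200 terms with the (deterministic,
#' tiny-variance) tail replaced by its mean. For large counts
#' (`b >= normal_threshold`) a moment-matched normal approximation is used;
#' with `b` that size the CLT error is negligible next to posterior
#' uncertainty. Symmetric in the sign of `z`.
#'
#' @param b Non-negative counts (vector); zero gives a zero draw.
#' @param z Tilting parameters (vector, recycled against `b`).
#' @param normal_threshold Count at or above which the normal approximation
#'   is used.
#' @param terms Number of gamma-series terms.
#' @return Numeric vector of PG draws, `length(b)` long.
#' @seealso [pg_mean()], [pg_var()] for the analytic moments.
#' @examples
#' set.seed(1)
#' mean(rpg(rep(1, 2000), 0.5)) # close to pg_mean(1, 0.5)
#' @export
rpg <- function(b, z = 0, normal_threshold = 30L, terms = 200L) {
  n <- max(length(b), length(z))
  b <- rep_len(b, n)
  z <- abs(rep_len(z, n))
  if (any(b < 0)) stop("b must be non-negative")
  out <- numeric(n)

  big <- which(b >= normal_threshold)
  if (length(big)) {
    m <- pg_mean(b[big], z[big])
    v <- pg_var(b[big], z[big])
    out[big] <- pmax(stats::rnorm(length(big), m, sqrt(v)), m * 1e-8)
  }

  small <- which(b > 0 & b < normal_threshold)
  if (length(small)) {
    bs <- b[small]; zs <- z[small]
    k <- seq_len(terms) - 0.5
    # denominators: terms x cells
    d <- outer(k^2, (zs / (2 * pi))^2, `+`)
    g <- matrix(stats::rgamma(terms * length(small), shape = rep(bs, each = terms)),
                nrow = terms)
    core <- colSums(g / d) / (2 * pi^2)
    # analytic tail mean: full sum of 1/d_k is pi^2 * tanh(z/2) / z
    full <- ifelse(zs < 1e-8, pi^2 / 2 * (1 - zs^2 / 12),
                   pi^2 * tanh(zs / 2) / zs)
    tail_mean <- bs * (full - colSums(1 / d)) / (2 * pi^2)
    out[small] <- core + tail_mean
  }
  out
}

#' @rdname rpg
#' @export
pg_mean <- function(b, z) {
  z <- abs(z)
  ifelse(z < 1e-4, b * (0.25 - z^2 / 48), b * tanh(z / 2) / (2 * z))
}

#' @rdname rpg
#' @export
pg_var <- function(b, z) {
  z <- abs(z)
  small <- z < 1e-3
  v <- numeric(length(z))
  zb <- z[!small]
  if (length(zb))
    v[!small] <- (2 * tanh(zb / 2) - zb / cosh(zb / 2)^2) / (4 * zb^3)
  v[small] <- 1 / 24
  rep_len(b, length(v)) * v
}
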
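#' Rank strata by prediction or interaction size
#'
#' Returns the `k` strata with the highest or lowest total predictions, or
#' the largest positive/negative interaction effects. Interaction modes
#' consider only significant interactions (95% interval excluding zero)
#' unless `significant_only = FALSE`. Ordering is deterministic; ties break
#' by stratum index.
#'
#' @param predictions A `maihda_predictions` data frame.
#' @param k Number of rows (`k = 0` gives an empty table).
#' @param mode One of `"highest"`, `"lowest"`, `"positive_interaction"`,
#'   `"negative_interaction"`.
#' @param significant_only Restrict interaction modes to significant rows.
#' @return The selected rows with a leading `rank` column.
#' @export
rank_strata <- function(predictions, k = 5L,
                        mode = c("highest", "lowest", "positive_interaction",
                                 "negative_interaction"),
                        significant_only = TRUE) {
  mode <- match.arg(mode)
  stopifnot(k >= 0)
  p <- as.data.frame(predictions)
  if (mode %in% c("positive_interaction", "negative_interaction") && significant_only)
    p <- p[p$significant, , drop = FALSE]
  ord <- switch(mode,
    highest = order(-p$total, p$stratum),
    lowest = order(p$total, p$stratum),
    positive_interaction = order(-p$interaction, p$stratum),
    negative_interaction = order(p$interaction, p$stratum)
  )
  p <- p[ord, , drop = FALSE]
  if (mode == "positive_interaction") p <- p[p$interaction > 0 | !significant_only, , drop = FALSE]
  if (mode == "negative_interaction") p <- p[p$interaction < 0 | !significant_only, , drop = FALSE]
  p <- utils::head(p, k)
  if (nrow(p)) cbind(rank = seq_len(nrow(p)), p, row.names = NULL)
  else cbind(rank = integer(0), p)
}

#' Correlation between two per-stratum outcomes
#'
#' Least-squares regression of one stratum-level prediction (typically mean
#' grams/day of drinkers) on another (typically percent current drinkers),
#' with Pearson correlation and outlier flagging: strata whose absolute
#' residual exceeds twice the residual standard deviation. The residual SD
#' uses the population formula (divide by n) by default; `"n-2"` selects the
#' regression-dof variant. The choice is recorded in the result.
#'
#' @param pred_x,pred_y `maihda_predictions` tables (or data frames with
#'   `stratum` and `total` columns) over the same strata.
#' @param residual_sd `"population"` or `"n-2"`.
#' @return Object of class `maihda_correlation`: `r`, `slope`, `intercept`,
#'   `residual_sd`, `residual_sd_mode`, `outliers` (stratum indices),
#'   and the point data (`x`, `y`, `residuals`, `labels`).
#' @export
correlate_outcomes <- function(pred_x, pred_y,
                               residual_sd = c("population", "n-2")) {
  residual_sd <- match.arg(residual_sd)
  x <- as.data.frame(pred_x); y <- as.data.frame(pred_y)
  m <- merge(x[, c("stratum", "label", "total")], y[, c("stratum", "total")],
             by = "stratum", suffixes = c("_x", "_y"))
  m <- m[order(m$stratum), ]
  if (nrow(m) < 3L) stop("at least 3 aligned strata are required")
  if (stats::var(m$total_x) == 0) stop("zero variance in x predictions")
  fit <- stats::lm.fit(cbind(1, m$total_x), m$total_y)
  res <- fit$residuals
  rsd <- if (residual_sd == "population") sqrt(mean(res^2))
         else sqrt(sum(res^2) / (nrow(m) - 2L))
  # guard against flagging pure floating-point noise on (near-)perfect fits
  eps <- 1e-10 * max(abs(m$total_y), 1)
  out <- structure(list(
    r = stats::cor(m$total_x, m$total_y),
    intercept = unname(fit$coefficients[1L]),
    slope = unname(fit$coefficients[2L]),
    residual_sd = rsd, residual_sd_mode = residual_sd,
    outliers = m$stratum[abs(res) > 2 * rsd + eps],
    stratum = m$stratum, labels = m$label,
    x = m$total_x, y = m$total_y, residuals = res
  ), class = "maihda_correlation")
  out
}

#' @export
print.maihda_correlation <- function(x, ...) {
  cat("Between-outcome correlation over ", length(x$x), " strata\n", sep = "")
  cat("  r = ", format(x$r, digits = 3), "; y = ",
      format(x$intercept, digits = 3), " + ", format(x$slope, digits = 3),
      " x\n", sep = "")
  cat("  residual SD = ", format(x$residual_sd, digits = 3), " (",
      x$residual_sd_mode, "); outliers (> 2 SD): ", length(x$outliers),
      "\n", sep = "")
  if (length(x$outliers))
    cat("  ", paste(x$labels[match(x$outliers, x$stratum)], collapse = "; "),
        "\n", sep = "")
  invisible(x)
}

#' Caterpillar plot of per-stratum predictions
#'
#' One point-and-interval pair per stratum: total predictions (filled, dark)
#' over additive-only predictions (open, light), ordered by the additive
#' estimate, optionally coloured by a grouping axis. Pure presentation over
#' an existing predictions table; nothing is re-estimated.
#'
#' @param predictions A `maihda_predictions` data frame (may be empty).
#' @param design Optional [strata_design()] supplying the grouping axis.
#' @param group Axis name used for colour groups (default `"sex"` if
#'   available).
#' @param family Outcome family, for the y-axis label.
#' @param file Optional path; when given, a PNG is written there and the
#'   path returned invisibly.
#' @param width,height,res PNG device settings.
#' @return The file path (if `file` given) or `NULL`, invisibly.
#' @export
caterpillar_plot <- function(predictions, design = NULL, group = NULL,
                             family = c("binomial", "lognormal"), file = NULL,
                             width = 1600, height = 700, res = 120) {
  family <- match.arg(family)
  p <- as.data.frame(predictions)
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height, res = res)
    on.exit(grDevices::dev.off())
  }
  ylab <- if (family == "binomial") "Current drinkers (%)" else "Mean consumption (g/day)"
  if (!nrow(p)) {
    plot(0, 0, type = "n", xlab = "Stratum (ordered by additive prediction)",
         ylab = ylab, main = "Stratum predictions")
    return(invisible(file))
  }
  grp <- rep(1L, nrow(p))
  if (!is.null(design)) {
    if (is.null(group)) group <- intersect("sex", names(design$axes))[1L]
    if (!is.null(group) && !is.na(group) && group %in% names(design$axes))
      grp <- match(design$strata[[group]][p$stratum], design$axes[[group]]$levels)
  }
  ord <- order(grp, p$additive, p$stratum)
  p <- p[ord, ]; grp <- grp[ord]
  xx <- seq_len(nrow(p))
  cols_tot <- c("#1f3d7a", "#a31515", "#1a6b1a", "#7a4d1f")
  cols_add <- c("#8fa8d9", "#e8a07a", "#93c793", "#d9b88f")
  ylim <- range(p$total_lower, p$total_upper, p$additive_lower, p$additive_upper)
  plot(xx, p$total, type = "n", ylim = ylim,
       xlab = "Stratum (grouped, ordered by additive prediction)", ylab = ylab,
       main = "Total vs additive-only stratum predictions")
  seg <- function(lo, hi, col) graphics::segments(xx, lo, xx, hi, col = col)
  seg(p$additive_lower, p$additive_upper, cols_add[(grp - 1L) %% 4L + 1L])
  graphics::points(xx, p$additive, pch = 1, col = cols_add[(grp - 1L) %% 4L + 1L])
  seg(p$total_lower, p$total_upper, cols_tot[(grp - 1L) %% 4L + 1L])
  graphics::points(xx, p$total, pch = 16, col = cols_tot[(grp - 1L) %% 4L + 1L])
  invisible(file)
}

#' Scatter plot of a between-outcome correlation
#'
#' Points per stratum, the fitted least-squares line, and outliers (beyond
#' twice the residual SD) highlighted in red.
#'
#' @param x A `maihda_correlation` object.
#' @param file Optional PNG path.
#' @param width,height,res PNG device settings.
#' @param ... Unused.
#' @return The file path (if written) or `NULL`, invisibly.
#' @export
plot.maihda_correlation <- function(x, file = NULL, width = 900, height = 700,
                                    res = 120, ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height, res = res)
    on.exit(grDevices::dev.off())
  }
  is_out <- x$stratum %in% x$outliers
  plot(x$x, x$y, pch = 16, col = ifelse(is_out, "red", "grey30"),
       xlab = "Predicted current drinkers (%)",
       ylab = "Predicted mean consumption (g/day)",
       main = sprintf("Between-outcome correlation (r = %.2f)", x$r))
  graphics::abline(x$intercept, x$slope, col = "steelblue", lwd = 2)
  if (any(is_out))
    graphics::text(x$x[is_out], x$y[is_out], x$labels[is_out], pos = 3, cex = 0.7,
                   col = "red")
  invisible(file)
}
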
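# Standardized group differences for small samples with unequal variances,
# and the EWB-EWBr association.
#
# The estimator standardizes the mean difference by the square root of the
# AVERAGE of the two group variances (not the pooled variance), which keeps it
# interpretable when the groups differ in spread, as neglect and control
# groups do dramatically on bias measures. The small-sample bias correction
# uses the exact gamma-function factor on Welch degrees of freedom.

# Exact small-sample correction factor J(df) = Gamma(df/2) /
# (sqrt(df/2) * Gamma((df-1)/2)); in (0, 1), -> 1 as df -> Inf.
correction_factor <- function(df) {
  exp(lgamma(df / 2) - lgamma((df - 1) / 2)) / sqrt(df / 2)
}

welch_df <- function(v1, n1, v2, n2) {
  (v1 / n1 + v2 / n2)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
}

# Noncentrality parameter ncp such that pt(t_obs, df, ncp) = prob.
ncp_root <- function(t_obs, df, prob) {
  f <- function(ncp) suppressWarnings(pt(t_obs, df, ncp = ncp)) - prob
  half <- abs(t_obs) + 50
  uniroot(f, interval = c(t_obs - half, t_obs + half), tol = 1e-10)$root
}

#' Standardized mean difference for unequal variances (d*_s / Hedges g*_s)
#'
#' Computes `d*_s = (mean_1 − mean_2) / sqrt((sd_1^2 + sd_2^2) / 2)`, the
#' standardized mean difference with the averaged-variance denominator, and
#' its small-sample bias-corrected counterpart `g*_s = J(df) * d*_s` with the
#' exact gamma-function factor on Welch degrees of freedom. The 95% confidence
#' interval inverts the noncentral-t distribution of the Welch t statistic on
#' the same degrees of freedom. Both the uncorrected and corrected values are
#' always reported; `apply_correction` selects which one the interval (and the
#' `estimate` field) refers to.
#'
#' @param mean_1,sd_1,n_1 Summary statistics of group 1 (conventionally the
#'   clinical group, so positive effects mean higher scores there).
#' @param mean_2,sd_2,n_2 Summary statistics of group 2 (controls).
#' @param apply_correction Report the bias-corrected `g*_s` as the headline
#'   estimate (default `TRUE`).
#' @param conf_level Confidence level of the interval.
#' @return An `effect_size_result`: `d_star_s`, `g_star_s`, `estimate`,
#'   `ci_low`, `ci_high`, `df_used` (Welch), `correction_factor`,
#'   `correction_applied`, `conf_level`.
#' @export
#' @examples
#' effect_size_gstar(12.72, 9.26, 10, 0.08, 1.22, 10)
effect_size_gstar <- function(mean_1, sd_1, n_1, mean_2, sd_2, n_2,
                              apply_correction = TRUE, conf_level = 0.95) {
  if (n_1 < 2 || n_2 < 2) {
    stop_nw("nw_insufficient_data_error", "both groups need n >= 2")
  }
  if (sd_1 < 0 || sd_2 < 0) stop_nw("nw_validation_error", "SDs must be >= 0")
  v1 <- sd_1^2; v2 <- sd_2^2
  if (v1 + v2 == 0) {
    stop_nw("nw_degenerate_error",
            "both group SDs are zero; the standardizer is undefined")
  }
  denom <- sqrt((v1 + v2) / 2)
  d <- (mean_1 - mean_2) / denom
  df <- welch_df(v1, n_1, v2, n_2)
  J <- correction_factor(df)
  g <- J * d

  # CI: the Welch t statistic is noncentral-t on df with ncp proportional to
  # the population effect; invert at the two tails and rescale to d units.
  se_t <- sqrt(v1 / n_1 + v2 / n_2)
  t_obs <- (mean_1 - mean_2) / se_t
  scale <- se_t / denom
  lo <- conf_level + (1 - conf_level) / 2
  hi <- (1 - conf_level) / 2
  ci_d <- sort(c(ncp_root(t_obs, df, lo), ncp_root(t_obs, df, hi))) * scale
  ci <- if (apply_correction) J * ci_d else ci_d

  structure(
    list(d_star_s = d, g_star_s = g,
         estimate = if (apply_correction) g else d,
         ci_low = ci[1], ci_high = ci[2],
         df_used = df, correction_factor = J,
         correction_applied = apply_correction, conf_level = conf_level),
    class = "effect_size_result"
  )
}

#' @export
print.effect_size_result <- function(x, ...) {
  cat(sprintf(
    "<effect_size_result> %s = %.3f [%.3f, %.3f] (%g%% CI, Welch df = %.2f)%s\n",
    if (x$correction_applied) "g*_s" else "d*_s",
    x$estimate, x$ci_low, x$ci_high, 100 * x$conf_level, x$df_used,
    sprintf("; d*_s = %.3f, g*_s = %.3f", x$d_star_s, x$g_star_s)
  ))
  invisible(x)
}

#' Squared Pearson association between two per-participant measures
#'
#' Returns the squared Pearson correlation together with the fitted
#' least-squares line of `y` on `x`, for reporting relationships such as the
#' one between the bisection and reproduction biases (EWB vs EWBr).
#'
#' @param x,y Paired per-participant scores (>= 3 complete pairs, each with
#'   nonzero variance). Pairs with a missing member are dropped.
#' @return An `association_result`: `r_squared`, `r`, `slope`, `intercept`,
#'   `n`.
#' @export
association_r2 <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    stop_nw("nw_insufficient_data_error",
            "need at least 3 complete pairs for the association")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_nw("nw_degenerate_error",
            "zero variance in one of the measures; correlation is undefined")
  }
  r <- cor(x, y)
  b <- coef(lm(y ~ x))
  structure(
    list(r_squared = r^2, r = r,
         slope = unname(b[2]), intercept = unname(b[1]), n = length(x)),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association_result> r^2 = %.3f (r = %.3f, n = %d); fit y = %.3f x + %.3f\n",
    x$r_squared, x$r, x$n, x$slope, x$intercept
  ))
  invisible(x)
}

#' Group summary table with effect sizes
#'
#' Builds the standard summary layer over a per-participant fit table: for
#' each bias measure, the neglect and control means and SDs plus the
#' standardized group difference from [effect_size_gstar()]. Measures or
#' groups with fewer than two usable values get `NA` in the affected columns.
#'
#' @param fits A per-participant tibble from [fit_cohort()] with a `group`
#'   column containing `"neglect"` and/or `"control"`.
#' @param measures Named character vector mapping display labels to columns of
#'   `fits`.
#' @param apply_correction Passed to [effect_size_gstar()].
#' @return A tibble with one row per measure: group ns, means, SDs,
#'   `d_star_s`, `g_star_s`, `ci_low`, `ci_high`.
#' @export
summarize_groups <- function(fits,
                             measures = c(DBE = "mean_dbe_mm", EWB = "ewb",
                                          EWBr = "ewbr"),
                             apply_correction = TRUE) {
  stopifnot(is.data.frame(fits), "group" %in% names(fits))
  one <- function(label, col) {
    x1 <- fits[[col]][fits$group == "neglect"]
    x2 <- fits[[col]][fits$group == "control"]
    x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
    es <- if (length(x1) >= 2 && length(x2) >= 2 &&
              (sd(x1) > 0 || sd(x2) > 0)) {
      effect_size_gstar(mean(x1), sd(x1), length(x1),
                        mean(x2), sd(x2), length(x2),
                        apply_correction = apply_correction)
    } else {
      NULL
    }
    tibble(
      measure = label,
      neglect_n = length(x1),
      neglect_mean = if (length(x1) > 0) mean(x1) else NA_real_,
      neglect_sd = if (length(x1) > 1) sd(x1) else NA_real_,
      control_n = length(x2),
      control_mean = if (length(x2) > 0) mean(x2) else NA_real_,
      control_sd = if (length(x2) > 1) sd(x2) else NA_real_,
      d_star_s = if (is.null(es)) NA_real_ else es$d_star_s,
      g_star_s = if (is.null(es)) NA_real_ else es$g_star_s,
      ci_low = if (is.null(es)) NA_real_ else es$ci_low,
      ci_high = if (is.null(es)) NA_real_ else es$ci_high
    )
  }
  dplyr::bind_rows(Map(one, names(measures), unname(measures)))
}

#' Render a group summary as aligned text
#'
#' @param summary A tibble from [summarize_groups()].
#' @param digits Digits for the standardized effects.
#' @return A character vector of lines (also printed when called
#'   interactively via `cat`).
#' @export
format_summary_table <- function(summary, digits = 2) {
  fmt_ms <- function(m, s) {
    ifelse(is.na(m), "-", sprintf("%.2f (%.2f)", m, ifelse(is.na(s), NaN, s)))
  }
  fmt_es <- function(g, lo, hi) {
    ifelse(is.na(g), "-",
           sprintf("%.*f [%.*f, %.*f]", digits, g, digits, lo, digits, hi))
  }
  body <- data.frame(
    Measure = summary$measure,
    `Neglect mean (SD)` = fmt_ms(summary$neglect_mean, summary$neglect_sd),
    `Control mean (SD)` = fmt_ms(summary$control_mean, summary$control_sd),
    `d*_s` = ifelse(is.na(summary$d_star_s), "-",
                    sprintf("%.*f", digits, summary$d_star_s)),
    `g*_s [95% CI]` = fmt_es(summary$g_star_s, summary$ci_low, summary$ci_high),
    check.names = FALSE
  )
  widths <- vapply(names(body), function(nm) {
    max(nchar(c(nm, body[[nm]])))
  }, integer(1))
  pad <- function(x, w) formatC(x, width = w, flag = "-")
  lines <- c(
    paste(mapply(pad, names(body), widths), collapse = "  "),
    paste(vapply(widths, function(w) strrep("-", w), character(1)),
          collapse = "  "),
    apply(body, 1, function(r) paste(mapply(pad, r, widths), collapse = "  "))
  )
  lines
}
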
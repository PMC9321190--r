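# Crawford-Howell single-case inference: comparing one score with a small
# control sample, treating the control statistics as estimates rather than
# population values.

check_controls <- function(control_values) {
  control_values <- control_values[!is.na(control_values)]
  n <- length(control_values)
  if (n < 2) {
    stop_nw("nw_insufficient_data_error",
            "need at least 2 control values for the modified t-test")
  }
  s <- sd(control_values)
  if (s == 0) {
    stop_nw("nw_degenerate_error",
            "control values have zero SD; the modified t-test is undefined")
  }
  list(values = control_values, n = n, mean = mean(control_values), sd = s)
}

#' Modified t-test of a single case against a control sample
#'
#' Computes `t = (case − control mean) / (control SD * sqrt(1 + 1/n))` on
#' `n − 1` degrees of freedom. Unlike a z-score against the control mean, the
#' inflation factor `sqrt(1 + 1/n)` and the t reference distribution account
#' for the control statistics being estimated from a small sample, so the
#' false-positive rate is exactly `alpha` for any control sample size.
#'
#' @param case_value The single case's score.
#' @param control_values Scores of the control sample (>= 2, non-degenerate).
#' @param alpha One-tailed significance level for the abnormality flag.
#' @param tail `"upper"` (case abnormally high; the relevant direction for
#'   left-neglect bias measures under the rightward-positive convention) or
#'   `"lower"`.
#' @return A `single_case_result`: `t_value`, `df`, `p_one_tailed`, `alpha`,
#'   `tail`, `exceeds_cutoff`.
#' @export
#' @examples
#' modified_t(4, c(1, 2, 3))  # t = 1.73, one-tailed p = 0.113
modified_t <- function(case_value, control_values, alpha = 0.05,
                       tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  ctl <- check_controls(control_values)
  if (!is.finite(case_value)) {
    stop_nw("nw_validation_error", "case_value must be finite")
  }
  t_value <- (case_value - ctl$mean) / (ctl$sd * sqrt(1 + 1 / ctl$n))
  df <- ctl$n - 1
  p <- pt(t_value, df, lower.tail = (tail == "lower"))
  structure(
    list(t_value = t_value, df = df, p_one_tailed = p,
         alpha = alpha, tail = tail, exceeds_cutoff = (p < alpha)),
    class = "single_case_result"
  )
}

#' @export
print.single_case_result <- function(x, ...) {
  cat(sprintf(
    "<single_case_result> t(%d) = %.4f, one-tailed p = %.4f (%s tail)%s\n",
    x$df, x$t_value, x$p_one_tailed, x$tail,
    if (x$exceeds_cutoff) sprintf(" *abnormal at alpha = %g*", x$alpha) else ""
  ))
  invisible(x)
}

#' Control-derived abnormality cut-off
#'
#' The score threshold at which the modified t-test becomes significant:
#' `mean + t_(1-alpha, n-1) * sd * sqrt(1 + 1/n)` for the upper tail (minus,
#' for the lower). A case exceeds the cut-off if and only if [modified_t()]
#' gives `p < alpha` in the same tail.
#'
#' @inheritParams modified_t
#' @return The threshold score (a single number).
#' @export
#' @examples
#' neglect_cutoff(rnorm(10, 0, 0.03))  # upper cut-off for an EWB-like measure
neglect_cutoff <- function(control_values, alpha = 0.05,
                           tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (alpha <= 0 || alpha >= 1) {
    stop_nw("nw_spec_error", "alpha must be in (0, 1)")
  }
  ctl <- check_controls(control_values)
  q <- qt(1 - alpha, ctl$n - 1) * ctl$sd * sqrt(1 + 1 / ctl$n)
  if (tail == "upper") ctl$mean + q else ctl$mean - q
}
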
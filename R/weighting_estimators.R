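# Per-participant estimation of endpoint weightings, EWB and EWBr.
#
# Bisection: OLS of the response position P on the left and right endpoint
# positions (with intercept); the coefficients are the endpoint weightings and
# EWB = w_right − w_left. When the design varies length only (L and R
# perfectly anti-correlated about a fixed centre) the two weightings are not
# separately identifiable, but EWB still is: it equals twice the OLS slope of
# directional bisection error on line length.
#
# Reproduction: per probed side, OLS slope of the reproduced position on the
# real endpoint position; EWBr = slope_right − slope_left.

#' Is a bisection design identifiable for the full regression?
#'
#' Checks the column rank of the centred `[L, R]` design matrix: the fit of
#' response on both endpoints needs L and R to vary with some independence.
#' Fixed-centre, length-manipulated designs make the centred columns exactly
#' anti-collinear and fail this check.
#'
#' @param trials A bisection trial table.
#' @param tol Rank tolerance: smallest/largest singular value below this is
#'   treated as rank-deficient.
#' @return `TRUE` if `fit_bisection_weightings()` can run.
#' @export
bisection_identifiable <- function(trials, tol = 1e-8) {
  if (nrow(trials) < 3) return(FALSE)
  X <- cbind(trials$left_mm - mean(trials$left_mm),
             trials$right_mm - mean(trials$right_mm))
  d <- svd(X, nu = 0, nv = 0)$d
  d[1] > 0 && d[2] / d[1] >= tol
}

#' Fit endpoint weightings from bisection responses
#'
#' Ordinary least squares of `response_mm` on `left_mm` and `right_mm` with an
#' intercept. The two coefficients are the left and right endpoint weightings;
#' their difference (right minus left) is the endpoint weightings bias EWB,
#' positive when the right endpoint dominates, as in left neglect.
#'
#' @param trials Bisection trials for one participant (>= 3, with a full-rank
#'   design; see [bisection_identifiable()]).
#' @return A `weighting_fit`: `w_left`, `w_right`, `intercept_mm`, `ewb`,
#'   `n_trials`, `r_squared`, `method = "full_regression"`.
#' @seealso [ewb_from_length_slope()] for length-only designs.
#' @export
#' @examples
#' pairs <- tibble::tibble(left_mm = runif(20, -150, -20),
#'                         right_mm = runif(20, 20, 150))
#' trials <- simulate_bisection(agent_params(0.5, 0.5), pairs)
#' fit_bisection_weightings(trials)
fit_bisection_weightings <- function(trials) {
  trials <- validate_bisection_trials(trials)
  if (nrow(trials) < 3) {
    stop_nw("nw_insufficient_data_error",
            "need at least 3 bisection trials to fit endpoint weightings")
  }
  if (!bisection_identifiable(trials)) {
    stop_nw("nw_identifiability_error", paste0(
      "left and right endpoints are collinear (e.g. all lines share one ",
      "centre); the separate weightings are not identifiable - use ",
      "ewb_from_length_slope() to recover EWB"
    ))
  }
  fit <- lm(response_mm ~ left_mm + right_mm, data = trials)
  b <- coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # noiseless fits are exact
  structure(
    list(w_left = unname(b["left_mm"]), w_right = unname(b["right_mm"]),
         intercept_mm = unname(b["(Intercept)"]),
         ewb = unname(b["right_mm"] - b["left_mm"]),
         n_trials = nrow(trials), r_squared = r2,
         method = "full_regression"),
    class = "weighting_fit"
  )
}

#' @export
print.weighting_fit <- function(x, ...) {
  cat(sprintf(
    "<weighting_fit> w_left %.3f, w_right %.3f, intercept %.2f mm, EWB %.3f (n = %d, R^2 = %.3f)\n",
    x$w_left, x$w_right, x$intercept_mm, x$ewb, x$n_trials, x$r_squared
  ))
  invisible(x)
}

#' Recover EWB from the line-length effect
#'
#' For designs that vary line length only, EWB equals twice the slope of the
#' best-fitting straight line relating directional bisection error to line
#' length: extending the line equally at both ends moves the response
#' rightward in proportion to the weighting asymmetry. Fits trial-level DBE on
#' trial-level length by default; `per_length_means = TRUE` fits the per-length
#' mean DBE instead (identical for balanced designs).
#'
#' @param trials Bisection trials for one participant spanning at least two
#'   distinct line lengths.
#' @param per_length_means Fit per-length mean DBE rather than trial-level DBE.
#' @return A `length_slope_fit`: `slope_dbe_per_mm`, `mean_dbe_mm`,
#'   `ewb = 2 * slope_dbe_per_mm`, `n_trials`, `r_squared`,
#'   `method = "length_slope"`.
#' @export
ewb_from_length_slope <- function(trials, per_length_means = FALSE) {
  m <- derive_bisection_measures(trials)
  if (nrow(m) < 3) {
    stop_nw("nw_insufficient_data_error",
            "need at least 3 bisection trials to fit the length slope")
  }
  if (length(unique(m$length_mm)) < 2) {
    stop_nw("nw_insufficient_design_error",
            "need at least 2 distinct line lengths to estimate the DBE-length slope")
  }
  dat <- if (per_length_means) {
    dplyr::summarise(dplyr::group_by(m, .data$length_mm),
                     dbe_mm = mean(.data$dbe_mm), .groups = "drop")
  } else {
    m
  }
  fit <- lm(dbe_mm ~ length_mm, data = dat)
  slope <- unname(coef(fit)["length_mm"])
  structure(
    list(slope_dbe_per_mm = slope, mean_dbe_mm = mean(m$dbe_mm),
         ewb = 2 * slope, n_trials = nrow(m),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         method = "length_slope"),
    class = "length_slope_fit"
  )
}

#' @export
print.length_slope_fit <- function(x, ...) {
  cat(sprintf(
    "<length_slope_fit> DBE-length slope %.4f, mean DBE %.2f mm, EWB %.3f (n = %d)\n",
    x$slope_dbe_per_mm, x$mean_dbe_mm, x$ewb, x$n_trials
  ))
  invisible(x)
}

#' Fit per-side reproduction weightings and EWBr
#'
#' Per probed side, the OLS slope of the reproduced position on that side's
#' real endpoint position quantifies the fidelity of its representation: 1 is
#' perfect tracking, 0 no tracking at all. EWBr is the right slope minus the
#' left slope, the reproduction analogue of EWB.
#'
#' @param trials Reproduction trials for one participant; each side needs >= 3
#'   probes with variation in the real endpoint position.
#' @param bivariate If `TRUE`, regress each side's reproduced position on both
#'   real endpoints and take the own-side coefficient (useful for
#'   independent-endpoint designs); default is the univariate per-side slope.
#' @return A `reproduction_fit`: `slope_left`, `slope_right`, `ewbr`,
#'   `n_left_trials`, `n_right_trials`.
#' @export
fit_reproduction_weightings <- function(trials, bivariate = FALSE) {
  trials <- validate_reproduction_trials(trials)
  one_side <- function(side) {
    sub <- trials[trials$probed_side == side, ]
    if (nrow(sub) < 3) {
      stop_nw("nw_insufficient_data_error", sprintf(
        "need at least 3 %s-endpoint probes (got %d)", side, nrow(sub)))
    }
    real <- if (side == "left") sub$left_mm else sub$right_mm
    if (sd(real) == 0) {
      stop_nw("nw_identifiability_error", sprintf(
        "real %s endpoint position does not vary; its slope is not estimable",
        side))
    }
    b <- if (bivariate) {
      fit <- lm(reproduced_mm ~ left_mm + right_mm, data = sub)
      coef(fit)[if (side == "left") "left_mm" else "right_mm"]
    } else {
      coef(lm(sub$reproduced_mm ~ real))[2]
    }
    list(slope = unname(b), n = nrow(sub))
  }
  l <- one_side("left")
  r <- one_side("right")
  structure(
    list(slope_left = l$slope, slope_right = r$slope,
         ewbr = r$slope - l$slope,
         n_left_trials = l$n, n_right_trials = r$n),
    class = "reproduction_fit"
  )
}

#' @export
print.reproduction_fit <- function(x, ...) {
  cat(sprintf(
    "<reproduction_fit> slope_left %.3f (n = %d), slope_right %.3f (n = %d), EWBr %.3f\n",
    x$slope_left, x$n_left_trials, x$slope_right, x$n_right_trials, x$ewbr
  ))
  invisible(x)
}

#' Fit one participant's bisection and reproduction measures
#'
#' Dispatches the bisection fit: the full endpoint-weighting regression when
#' the design is identifiable, else the length-slope route (`method =
#' "auto"`). The reproduction fit is returned alongside, or `NULL` when no
#' reproduction trials are supplied.
#'
#' @param bisection Bisection trials for one participant.
#' @param reproduction Reproduction trials for the same participant, or `NULL`.
#' @param method `"auto"`, `"full_regression"` or `"length_slope"`.
#' @return A list of class `participant_fit` with elements `bisection` (a
#'   `weighting_fit` or `length_slope_fit`) and `reproduction` (a
#'   `reproduction_fit` or `NULL`).
#' @export
fit_participant <- function(bisection, reproduction = NULL,
                            method = c("auto", "full_regression", "length_slope")) {
  method <- match.arg(method)
  bfit <- switch(method,
    full_regression = fit_bisection_weightings(bisection),
    length_slope = ewb_from_length_slope(bisection),
    auto = if (bisection_identifiable(bisection)) {
      fit_bisection_weightings(bisection)
    } else {
      ewb_from_length_slope(bisection)
    }
  )
  rfit <- if (!is.null(reproduction) && nrow(reproduction) > 0) {
    fit_reproduction_weightings(reproduction)
  } else {
    NULL
  }
  structure(list(bisection = bfit, reproduction = rfit),
            class = "participant_fit")
}

#' Fit every participant in a cohort
#'
#' Splits the trial tables by participant and applies [fit_participant()],
#' returning one row per participant with the per-trial mean DBE, the EWB
#' estimate (and, where identifiable, the separate weightings), and the
#' reproduction slopes and EWBr where reproduction trials exist.
#'
#' @param bisection Bisection trials for any number of participants.
#' @param reproduction Optional reproduction trials.
#' @inheritParams fit_participant
#' @return A tibble with columns `participant_id`, `group`, `method`,
#'   `w_left`, `w_right`, `intercept_mm`, `mean_dbe_mm`, `ewb`, `r_squared`,
#'   `slope_left`, `slope_right`, `ewbr`, `n_bisection`, `n_repro_left`,
#'   `n_repro_right` (`NA` where a quantity is not estimable or absent).
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(seed = 1))
#' fit_cohort(cohort$bisection, cohort$reproduction)
fit_cohort <- function(bisection, reproduction = NULL, method = "auto") {
  bisection <- validate_bisection_trials(bisection)
  if (!is.null(reproduction)) {
    reproduction <- validate_reproduction_trials(reproduction)
  }
  ids <- unique(bisection$participant_id)
  rows <- lapply(ids, function(id) {
    b <- bisection[bisection$participant_id == id, ]
    r <- if (is.null(reproduction)) NULL else {
      reproduction[reproduction$participant_id == id, ]
    }
    pf <- fit_participant(b, r, method = method)
    bf <- pf$bisection
    rf <- pf$reproduction
    full <- identical(bf$method, "full_regression")
    tibble(
      participant_id = id,
      group = b$group[1],
      method = bf$method,
      w_left = if (full) bf$w_left else NA_real_,
      w_right = if (full) bf$w_right else NA_real_,
      intercept_mm = if (full) bf$intercept_mm else NA_real_,
      mean_dbe_mm = mean(derive_bisection_measures(b)$dbe_mm),
      ewb = bf$ewb,
      r_squared = bf$r_squared,
      slope_left = if (is.null(rf)) NA_real_ else rf$slope_left,
      slope_right = if (is.null(rf)) NA_real_ else rf$slope_right,
      ewbr = if (is.null(rf)) NA_real_ else rf$ewbr,
      n_bisection = nrow(b),
      n_repro_left = if (is.null(rf)) 0L else rf$n_left_trials,
      n_repro_right = if (is.null(rf)) 0L else rf$n_right_trials
    )
  })
  dplyr::bind_rows(rows)
}

#' Write per-participant fits to CSV
#'
#' @param fits The tibble returned by [fit_cohort()] (possibly with cut-off
#'   flag columns appended by [run_pipeline()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fits_csv <- function(fits, path) {
  readr::write_csv(round6(fits), path, progress = FALSE)
  invisible(path)
}
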
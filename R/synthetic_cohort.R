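# Generative simulator of bisection and endpoint-reproduction behaviour under
# the endpoint-weightings model.
#
# A linear agent responds P = w_left*L + w_right*R + intercept + noise. An
# ideal bisector has (w_left, w_right) = (0.5, 0.5); a severely neglecting,
# right-anchored agent has (0, 1) with a negative intercept, placing the mark
# at a fixed distance inside the right endpoint. Reproduction follows either a
# veridical model (reproduced = real endpoint + noise) or the subjective-line
# model, in which the left endpoint is extrapolated symmetrically about the
# chosen midpoint: reproduced left = 2P − R.

#' Parameters of a single simulated responder
#'
#' @param w_left,w_right Dimensionless endpoint weightings of the bisection
#'   response model `P = w_left*L + w_right*R + intercept_mm + noise`. Any
#'   finite values are allowed; 0.5/0.5 is the ideal bisector.
#' @param intercept_mm Constant term of the response model (mm).
#' @param motor_sd_mm SD of Gaussian bisection response noise (mm, >= 0).
#' @param repro_model `"veridical"` (reproduced = real endpoint + noise) or
#'   `"subjective_line"` (reproduced right = R + noise; reproduced left =
#'   2P − R + noise, the point symmetric to R about the chosen midpoint).
#' @param repro_sd_mm SD of Gaussian reproduction noise (mm, >= 0).
#' @return An `agent_params` object (a validated list).
#' @export
#' @examples
#' agent_params(0, 1, -100)  # right-anchored: mark always 100 mm left of R
agent_params <- function(w_left = 0.5, w_right = 0.5, intercept_mm = 0,
                         motor_sd_mm = 0,
                         repro_model = c("veridical", "subjective_line"),
                         repro_sd_mm = 0) {
  repro_model <- match.arg(repro_model)
  if (!is.finite(w_left) || !is.finite(w_right) || !is.finite(intercept_mm)) {
    stop_nw("nw_spec_error", "agent weightings and intercept must be finite")
  }
  if (motor_sd_mm < 0 || repro_sd_mm < 0) {
    stop_nw("nw_spec_error", "noise SDs must be >= 0")
  }
  structure(
    list(w_left = w_left, w_right = w_right, intercept_mm = intercept_mm,
         motor_sd_mm = motor_sd_mm, repro_model = repro_model,
         repro_sd_mm = repro_sd_mm),
    class = "agent_params"
  )
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf(
    "<agent_params> P = %.3g*L + %.3g*R + %.3g mm, motor SD %.3g mm, %s reproduction (SD %.3g mm)\n",
    x$w_left, x$w_right, x$intercept_mm, x$motor_sd_mm,
    x$repro_model, x$repro_sd_mm
  ))
  invisible(x)
}

#' Stimulus design for simulated trials
#'
#' Two modes. `length_manipulated` presents lines of fixed lengths centred at
#' `centre_mm` (optionally jittered), the classical clinical design; left and
#' right endpoints then covary perfectly, so only the composite bias EWB is
#' estimable (via the length slope). `independent_endpoints` samples L and R
#' independently from disjoint uniform ranges, the design needed to estimate
#' the two weightings separately.
#'
#' @param mode `"length_manipulated"` or `"independent_endpoints"`.
#' @param lengths_mm Line lengths (mm, > 0) for the length mode.
#' @param reps_per_condition Repetitions per length (length mode), or total
#'   number of trials (independent mode, which has a single condition).
#' @param centre_mm,centre_jitter_sd_mm Line-centre distribution (length mode):
#'   centre ~ Normal(`centre_mm`, `centre_jitter_sd_mm`).
#' @param left_range_mm,right_range_mm Uniform sampling intervals for L and R
#'   (independent mode); `max(left_range_mm)` must be `< min(right_range_mm)`
#'   so every line has positive length.
#' @param probe_both_endpoints If `TRUE` the reproduction phase probes both
#'   endpoints of every bisection trial; otherwise one side at random.
#' @return A `design_spec` object.
#' @export
design_spec <- function(mode = c("length_manipulated", "independent_endpoints"),
                        lengths_mm = c(25, 100, 250),
                        reps_per_condition = 4L,
                        centre_mm = 0, centre_jitter_sd_mm = 0,
                        left_range_mm = c(-150, -20),
                        right_range_mm = c(20, 150),
                        probe_both_endpoints = TRUE) {
  mode <- match.arg(mode)
  if (reps_per_condition < 1) {
    stop_nw("nw_spec_error", "reps_per_condition must be >= 1")
  }
  if (mode == "length_manipulated") {
    if (length(lengths_mm) == 0 || any(!is.finite(lengths_mm)) ||
        any(lengths_mm <= 0)) {
      stop_nw("nw_spec_error", "lengths_mm must be a non-empty set of positive lengths")
    }
    if (centre_jitter_sd_mm < 0) {
      stop_nw("nw_spec_error", "centre_jitter_sd_mm must be >= 0")
    }
  } else {
    left_range_mm <- sort(left_range_mm)
    right_range_mm <- sort(right_range_mm)
    if (length(left_range_mm) != 2 || length(right_range_mm) != 2 ||
        max(left_range_mm) >= min(right_range_mm)) {
      stop_nw("nw_spec_error",
              "independent mode needs max(left_range_mm) < min(right_range_mm)")
    }
  }
  structure(
    list(mode = mode, lengths_mm = lengths_mm,
         reps_per_condition = as.integer(reps_per_condition),
         centre_mm = centre_mm, centre_jitter_sd_mm = centre_jitter_sd_mm,
         left_range_mm = left_range_mm, right_range_mm = right_range_mm,
         probe_both_endpoints = isTRUE(probe_both_endpoints)),
    class = "design_spec"
  )
}

#' Draw endpoint pairs for one session
#'
#' Deterministic given the R random seed in force. Length mode yields
#' `length(lengths_mm) * reps_per_condition` pairs `(centre − len/2,
#' centre + len/2)`; independent mode yields `reps_per_condition` pairs with
#' L and R drawn independently and uniformly from their ranges.
#'
#' @param design A [design_spec()].
#' @return A tibble with columns `left_mm`, `right_mm`.
#' @export
generate_design <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  if (design$mode == "length_manipulated") {
    len <- rep(design$lengths_mm, each = design$reps_per_condition)
    centre <- if (design$centre_jitter_sd_mm > 0) {
      design$centre_mm + rnorm(length(len), 0, design$centre_jitter_sd_mm)
    } else {
      rep(design$centre_mm, length(len))
    }
    tibble(left_mm = centre - len / 2, right_mm = centre + len / 2)
  } else {
    n <- design$reps_per_condition
    tibble(
      left_mm = runif(n, design$left_range_mm[1], design$left_range_mm[2]),
      right_mm = runif(n, design$right_range_mm[1], design$right_range_mm[2])
    )
  }
}

#' Simulate bisection responses of a linear agent
#'
#' For each endpoint pair, `response_mm = w_left*left + w_right*right +
#' intercept + Normal(0, motor_sd_mm)`.
#'
#' @param agent An [agent_params()].
#' @param pairs A tibble of `left_mm`, `right_mm` endpoint pairs, e.g. from
#'   [generate_design()].
#' @param participant_id,group Labels stamped onto the trials.
#' @return A validated bisection trial tibble.
#' @export
simulate_bisection <- function(agent, pairs, participant_id = "sim",
                               group = "unknown") {
  stopifnot(inherits(agent, "agent_params"))
  n <- nrow(pairs)
  noise <- if (agent$motor_sd_mm > 0) rnorm(n, 0, agent$motor_sd_mm) else rep(0, n)
  validate_bisection_trials(tibble(
    participant_id = participant_id,
    group = group,
    trial_index = seq_len(n),
    left_mm = pairs$left_mm,
    right_mm = pairs$right_mm,
    response_mm = agent$w_left * pairs$left_mm +
      agent$w_right * pairs$right_mm + agent$intercept_mm + noise
  ))
}

#' Simulate endpoint reproduction following bisection
#'
#' Under the veridical model both endpoints are reproduced at their real
#' positions plus noise. Under the subjective-line model the right endpoint is
#' reproduced veridically but the left endpoint is reconstructed as the mirror
#' of the right endpoint about the chosen midpoint, `2P − R`: the agent
#' behaves as if the line extended equally to either side of its bisection
#' mark, so the reproduced left endpoint ignores the real left endpoint.
#'
#' @param agent An [agent_params()].
#' @param trials Bisection trials supplying `(left_mm, right_mm,
#'   response_mm)` per trial.
#' @param probe_both_endpoints If `TRUE` (default) emit one left and one right
#'   probe per bisection trial; otherwise one side chosen at random per trial.
#' @return A validated reproduction trial tibble.
#' @export
simulate_reproduction <- function(agent, trials, probe_both_endpoints = TRUE) {
  stopifnot(inherits(agent, "agent_params"))
  trials <- validate_bisection_trials(trials)
  n <- nrow(trials)
  if (probe_both_endpoints) {
    idx <- rep(seq_len(n), each = 2)
    side <- rep(c("left", "right"), times = n)
  } else {
    idx <- seq_len(n)
    side <- ifelse(runif(n) < 0.5, "left", "right")
  }
  L <- trials$left_mm[idx]
  R <- trials$right_mm[idx]
  P <- trials$response_mm[idx]
  target <- ifelse(side == "right", R,
                   if (agent$repro_model == "veridical") L else NA_real_)
  if (agent$repro_model == "subjective_line") {
    target[side == "left"] <- (2 * P - R)[side == "left"]
  }
  m <- length(idx)
  noise <- if (agent$repro_sd_mm > 0) rnorm(m, 0, agent$repro_sd_mm) else rep(0, m)
  validate_reproduction_trials(tibble(
    participant_id = trials$participant_id[idx],
    group = trials$group[idx],
    trial_index = trials$trial_index[idx],
    left_mm = L,
    right_mm = R,
    bisection_response_mm = P,
    probed_side = side,
    reproduced_mm = target + noise
  ))
}

#' Population distribution of agent parameters for one group
#'
#' Each agent's weightings and intercept are drawn independently from normal
#' distributions; the noise SDs and the reproduction model are shared by the
#' whole group.
#'
#' @param w_left,w_left_sd,w_right,w_right_sd Mean and SD of the endpoint
#'   weightings across agents.
#' @param intercept_mm,intercept_sd_mm Mean and SD of the response intercept.
#' @param motor_sd_mm,repro_sd_mm Within-agent noise SDs (mm), common to the
#'   group.
#' @param repro_model Reproduction model for the group.
#' @return An `agent_population` object.
#' @export
agent_population <- function(w_left = 0.5, w_left_sd = 0,
                             w_right = 0.5, w_right_sd = 0,
                             intercept_mm = 0, intercept_sd_mm = 0,
                             motor_sd_mm = 2,
                             repro_model = c("veridical", "subjective_line"),
                             repro_sd_mm = motor_sd_mm) {
  repro_model <- match.arg(repro_model)
  if (any(c(w_left_sd, w_right_sd, intercept_sd_mm, motor_sd_mm, repro_sd_mm) < 0)) {
    stop_nw("nw_spec_error", "population SDs must be >= 0")
  }
  structure(
    list(w_left = w_left, w_left_sd = w_left_sd,
         w_right = w_right, w_right_sd = w_right_sd,
         intercept_mm = intercept_mm, intercept_sd_mm = intercept_sd_mm,
         motor_sd_mm = motor_sd_mm, repro_model = repro_model,
         repro_sd_mm = repro_sd_mm),
    class = "agent_population"
  )
}

draw_agent <- function(pop) {
  stopifnot(inherits(pop, "agent_population"))
  agent_params(
    w_left = rnorm(1, pop$w_left, pop$w_left_sd),
    w_right = rnorm(1, pop$w_right, pop$w_right_sd),
    intercept_mm = rnorm(1, pop$intercept_mm, pop$intercept_sd_mm),
    motor_sd_mm = pop$motor_sd_mm,
    repro_model = pop$repro_model,
    repro_sd_mm = pop$repro_sd_mm
  )
}

#' Default control-group population
#'
#' Near-ideal bisectors (weightings 0.5 ± 0.02 each), intercept 0 ± 1 mm,
#' motor SD 2 mm, veridical reproduction with SD 2 mm.
#'
#' @return An [agent_population()].
#' @export
control_population <- function() {
  agent_population(
    w_left = 0.5, w_left_sd = 0.02,
    w_right = 0.5, w_right_sd = 0.02,
    intercept_mm = 0, intercept_sd_mm = 1,
    motor_sd_mm = 2, repro_model = "veridical", repro_sd_mm = 2
  )
}

#' Default neglect-group population
#'
#' Strongly right-dominated responders: weightings 0.05 ± 0.05 (left) and
#' 0.75 ± 0.10 (right), so the mean bias EWB is 0.70; intercept −12 ± 3 mm,
#' chosen so that on 25 mm lines the expected bisection error is leftward
#' (the short-line cross-over) while remaining strongly rightward on 100 and
#' 250 mm lines; motor SD 4 mm; subjective-line reproduction with SD 4 mm.
#'
#' @return An [agent_population()].
#' @export
neglect_population <- function() {
  agent_population(
    w_left = 0.05, w_left_sd = 0.05,
    w_right = 0.75, w_right_sd = 0.10,
    intercept_mm = -12, intercept_sd_mm = 3,
    motor_sd_mm = 4, repro_model = "subjective_line", repro_sd_mm = 4
  )
}

#' Specification of a simulated two-group cohort
#'
#' @param n_per_group Number of agents per group (>= 1).
#' @param control,neglect [agent_population()]s for the two groups.
#' @param design A [design_spec()], shared by all agents.
#' @param seed Integer root seed; the whole cohort is a pure function of the
#'   spec, and each agent gets a deterministically derived substream so a
#'   subset can be regenerated without touching the others.
#' @return A `cohort_spec` object.
#' @seealso [default_cohort_spec()], [generate_cohort()]
#' @export
cohort_spec <- function(n_per_group = 10L,
                        control = control_population(),
                        neglect = neglect_population(),
                        design = design_spec(),
                        seed = 1L) {
  if (n_per_group < 1) stop_nw("nw_spec_error", "n_per_group must be >= 1")
  stopifnot(inherits(control, "agent_population"),
            inherits(neglect, "agent_population"),
            inherits(design, "design_spec"))
  structure(
    list(n_per_group = as.integer(n_per_group), control = control,
         neglect = neglect, design = design, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Default simulated study: two groups of ten
#'
#' Ten control and ten neglect agents, lines of 25, 100 and 250 mm with four
#' repetitions each at a fixed centre, both endpoints probed after every
#' bisection (12 bisection + 24 reproduction trials per participant).
#'
#' @param seed Integer root seed.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(seed = 1L) {
  cohort_spec(
    n_per_group = 10L,
    control = control_population(),
    neglect = neglect_population(),
    design = design_spec("length_manipulated",
                         lengths_mm = c(25, 100, 250),
                         reps_per_condition = 4L,
                         centre_mm = 0, centre_jitter_sd_mm = 0,
                         probe_both_endpoints = TRUE),
    seed = seed
  )
}

# Deterministic per-agent substream seeds, kept within 32-bit integer range.
agent_seed <- function(root, k) {
  s <- (abs(as.numeric(root)) %% 2147483647) + 1
  s <- (s * 48271) %% 2147483647
  as.integer((s + k * 104729) %% 2147483647)
}

#' Simulate a full two-group cohort
#'
#' Draws `n_per_group` agents per group from the stated populations and runs
#' every agent through the same design: a fresh endpoint layout, a bisection
#' response per trial, and reproduction probes per the design's
#' `probe_both_endpoints` flag. Fully reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort` with elements `bisection` and
#'   `reproduction` (trial tibbles in the CSV schemas) and `agents` (the true
#'   drawn parameters per participant, for simulation studies).
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(seed = 1))
#' dplyr::count(cohort$bisection, group)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- list(control = spec$control, neglect = spec$neglect)
  prefix <- c(control = "C", neglect = "N")
  bis <- list(); rep_ <- list(); agents <- list()
  k <- 0L
  for (g in names(groups)) {
    for (i in seq_len(spec$n_per_group)) {
      k <- k + 1L
      set.seed(agent_seed(spec$seed, k))
      id <- sprintf("%s%02d", prefix[[g]], i)
      agent <- draw_agent(groups[[g]])
      pairs <- generate_design(spec$design)
      b <- simulate_bisection(agent, pairs, participant_id = id, group = g)
      r <- simulate_reproduction(agent, b,
        probe_both_endpoints = spec$design$probe_both_endpoints)
      bis[[k]] <- b; rep_[[k]] <- r
      agents[[k]] <- tibble(
        participant_id = id, group = g,
        w_left = agent$w_left, w_right = agent$w_right,
        intercept_mm = agent$intercept_mm, motor_sd_mm = agent$motor_sd_mm,
        repro_model = agent$repro_model, repro_sd_mm = agent$repro_sd_mm
      )
    }
  }
  structure(
    list(bisection = dplyr::bind_rows(bis),
         reproduction = dplyr::bind_rows(rep_),
         agents = dplyr::bind_rows(agents)),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d participants, %d bisection and %d reproduction trials\n",
    length(unique(x$bisection$participant_id)),
    nrow(x$bisection), nrow(x$reproduction)
  ))
  invisible(x)
}

#' Read a cohort specification from a JSON config file
#'
#' The JSON mirrors the [cohort_spec()] fields: `n_per_group`, `seed`,
#' `design` (fields of [design_spec()]) and `control` / `neglect` (fields of
#' [agent_population()]). Missing fields take the package defaults.
#'
#' @param path Path to a JSON file.
#' @return A [cohort_spec()].
#' @export
read_cohort_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  pop <- function(defaults, lst) {
    if (is.null(lst)) return(defaults)
    args <- utils::modifyList(unclass(defaults), lst)
    do.call(agent_population, args)
  }
  des <- if (is.null(cfg$design)) design_spec() else {
    do.call(design_spec, cfg$design)
  }
  cohort_spec(
    n_per_group = cfg$n_per_group %||% 10L,
    control = pop(control_population(), cfg$control),
    neglect = pop(neglect_population(), cfg$neglect),
    design = des,
    seed = cfg$seed %||% 1L
  )
}
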
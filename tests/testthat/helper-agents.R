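# Shared builders for estimator and simulator tests.

# Endpoint pairs with L and R varied independently (full-rank design).
independent_pairs <- function(n = 20) {
  tibble::tibble(
    left_mm = runif(n, -150, -20),
    right_mm = runif(n, 20, 150)
  )
}

# Fixed-centre, length-manipulated pairs (rank-deficient for the full fit).
length_pairs <- function(lengths = c(25, 100, 250), reps = 4, centre = 0) {
  len <- rep(lengths, each = reps)
  tibble::tibble(left_mm = centre - len / 2, right_mm = centre + len / 2)
}

# Noiseless linear responses for arbitrary weightings.
linear_trials <- function(pairs, w_left, w_right, intercept = 0,
                          id = "sim", group = "unknown") {
  simulate_bisection(
    agent_params(w_left, w_right, intercept, motor_sd_mm = 0),
    pairs, participant_id = id, group = group
  )
}

# Independent OLS oracle: solve the normal equations directly, without lm().
normal_equation_fit <- function(trials) {
  X <- cbind(1, trials$left_mm, trials$right_mm)
  beta <- solve(t(X) %*% X, t(X) %*% trials$response_mm)
  c(intercept = beta[1], w_left = beta[2], w_right = beta[3])
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
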
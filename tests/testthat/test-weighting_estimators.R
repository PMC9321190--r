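test_that("the full regression recovers noiseless linear agents exactly", {
  set.seed(101)
  pairs <- independent_pairs(20)

  ideal <- fit_bisection_weightings(linear_trials(pairs, 0.5, 0.5, 0))
  expect_equal(ideal$w_left, 0.5, tolerance = 1e-9)
  expect_equal(ideal$w_right, 0.5, tolerance = 1e-9)
  expect_equal(ideal$ewb, 0, tolerance = 1e-9)
  expect_equal(ideal$method, "full_regression")

  anchored <- fit_bisection_weightings(linear_trials(pairs, 0, 1, -100))
  expect_equal(anchored$w_left, 0, tolerance = 1e-9)
  expect_equal(anchored$w_right, 1, tolerance = 1e-9)
  expect_equal(anchored$intercept_mm, -100, tolerance = 1e-9)
  expect_equal(anchored$ewb, 1, tolerance = 1e-9)

  for (i in 1:5) {
    w <- runif(2, -1, 2); c0 <- runif(1, -60, 60)
    fit <- fit_bisection_weightings(linear_trials(pairs, w[1], w[2], c0))
    expect_equal(c(fit$w_left, fit$w_right, fit$intercept_mm),
                 c(w[1], w[2], c0), tolerance = 1e-9)
    expect_equal(fit$ewb, fit$w_right - fit$w_left)
  }
})

test_that("full regression matches the normal-equation oracle on noisy data", {
  set.seed(102)
  pairs <- independent_pairs(60)
  b <- simulate_bisection(agent_params(0.1, 0.8, 5, motor_sd_mm = 2), pairs)
  fit <- fit_bisection_weightings(b)
  oracle <- normal_equation_fit(b)
  expect_equal(fit$w_left, oracle[["w_left"]], tolerance = 1e-9)
  expect_equal(fit$w_right, oracle[["w_right"]], tolerance = 1e-9)
  expect_equal(fit$intercept_mm, oracle[["intercept"]], tolerance = 1e-9)
  # severe-neglect pattern: left weighting close to zero
  expect_lt(abs(fit$w_left - 0.1), 0.05)
  expect_lt(abs(fit$w_right - 0.8), 0.05)
})

test_that("degenerate bisection designs raise classed errors", {
  centred <- linear_trials(length_pairs(), 0.3, 0.8, -5)
  expect_error(fit_bisection_weightings(centred),
               class = "nw_identifiability_error")
  expect_error(fit_bisection_weightings(centred), "ewb_from_length_slope")
  expect_false(bisection_identifiable(centred))

  set.seed(103)
  two <- linear_trials(independent_pairs(2), 0.5, 0.5)
  expect_error(fit_bisection_weightings(two),
               class = "nw_insufficient_data_error")
})

test_that("the length-slope route recovers EWB from length-only designs", {
  anchored <- linear_trials(length_pairs(), 0, 1, -100)
  fit <- ewb_from_length_slope(anchored)
  expect_equal(fit$slope_dbe_per_mm, 0.5, tolerance = 1e-9)
  expect_equal(fit$ewb, 1, tolerance = 1e-9)
  expect_equal(fit$ewb, 2 * fit$slope_dbe_per_mm)

  ideal <- linear_trials(length_pairs(), 0.5, 0.5, 0)
  expect_equal(ewb_from_length_slope(ideal)$ewb, 0, tolerance = 1e-9)

  one_length <- linear_trials(length_pairs(lengths = 100, reps = 6), 0.5, 0.5)
  expect_error(ewb_from_length_slope(one_length),
               class = "nw_insufficient_design_error")
})

test_that("both EWB estimators agree exactly for noiseless linear agents", {
  # algebraic identity: at a fixed centre, DBE = ((w_r - w_l)/2) * length +
  # (w_l + w_r - 1) * centre + c, so 2 * slope = w_r - w_l
  set.seed(104)
  for (i in 1:5) {
    w <- runif(2, -0.5, 1.5); c0 <- runif(1, -30, 30)
    centred <- linear_trials(length_pairs(centre = runif(1, -40, 40)),
                             w[1], w[2], c0)
    ls <- ewb_from_length_slope(centred)
    expect_equal(ls$ewb, w[2] - w[1], tolerance = 1e-9)

    full <- fit_bisection_weightings(linear_trials(independent_pairs(12),
                                                   w[1], w[2], c0))
    expect_equal(ls$ewb, full$ewb, tolerance = 1e-9)
  }
})

test_that("means-based and trial-level length slopes coincide on balanced designs", {
  set.seed(105)
  b <- simulate_bisection(agent_params(0.1, 0.8, -10, motor_sd_mm = 4),
                          length_pairs(reps = 8))
  expect_equal(ewb_from_length_slope(b)$ewb,
               ewb_from_length_slope(b, per_length_means = TRUE)$ewb,
               tolerance = 1e-9)
})

test_that("reproduction slopes quantify endpoint tracking", {
  set.seed(106)
  pairs <- independent_pairs(30)
  b <- simulate_bisection(agent_params(0.5, 0.5), pairs)

  verid <- simulate_reproduction(agent_params(0.5, 0.5), b)
  fit <- fit_reproduction_weightings(verid)
  expect_equal(fit$slope_left, 1, tolerance = 1e-9)
  expect_equal(fit$slope_right, 1, tolerance = 1e-9)
  expect_equal(fit$ewbr, 0, tolerance = 1e-9)

  # constant offsets are absorbed by the intercept
  offset <- dplyr::mutate(verid, reproduced_mm = reproduced_mm + 17)
  ofit <- fit_reproduction_weightings(offset)
  expect_equal(c(ofit$slope_left, ofit$slope_right), c(1, 1), tolerance = 1e-9)
  expect_equal(ofit$ewbr, 0, tolerance = 1e-9)

  # subjective-line agent anchored to the right endpoint: its reproduced left
  # endpoint tracks R - 200, so the slope on the real (independent) left
  # endpoint is zero up to sampling noise, while the right slope is exactly 1
  anchor <- agent_params(0, 1, -100, repro_model = "subjective_line")
  b2 <- simulate_bisection(anchor, independent_pairs(60))
  r2 <- simulate_reproduction(anchor, b2)
  # slope_left is zero up to sampling noise: sd(R)/sd(L) ~ 1, so its MC SD is
  # about 1/sqrt(n - 2) ~ 0.13; bound at 3 SDs
  fit2 <- fit_reproduction_weightings(r2)
  expect_lt(abs(fit2$slope_left), 0.4)
  expect_equal(fit2$slope_right, 1, tolerance = 1e-9)
  expect_lt(abs(fit2$ewbr - 1), 0.4)
})

test_that("unidentifiable or sparse reproduction data raise classed errors", {
  set.seed(107)
  pairs <- length_pairs()  # left endpoint varies; keep right fixed below
  b <- simulate_bisection(agent_params(0.5, 0.5), pairs)
  r <- simulate_reproduction(agent_params(0.5, 0.5), b)
  r_fixed <- dplyr::mutate(r, right_mm = 200, left_mm = left_mm - 100)
  expect_error(fit_reproduction_weightings(r_fixed),
               class = "nw_identifiability_error")
  expect_error(fit_reproduction_weightings(r[r$probed_side == "left", ][1:2, ]),
               class = "nw_insufficient_data_error")
})

test_that("fit_participant dispatches on design identifiability", {
  set.seed(108)
  agent <- agent_params(0.1, 0.8, -10, motor_sd_mm = 2,
                        repro_model = "subjective_line", repro_sd_mm = 2)

  b_len <- simulate_bisection(agent, length_pairs())
  r_len <- simulate_reproduction(agent, b_len)
  pf <- fit_participant(b_len, r_len)
  expect_s3_class(pf$bisection, "length_slope_fit")
  expect_s3_class(pf$reproduction, "reproduction_fit")

  b_ind <- simulate_bisection(agent, independent_pairs(30))
  pf2 <- fit_participant(b_ind, simulate_reproduction(agent, b_ind))
  expect_s3_class(pf2$bisection, "weighting_fit")

  pf3 <- fit_participant(b_ind, NULL)
  expect_null(pf3$reproduction)
  row <- fit_cohort(b_ind)
  expect_true(is.na(row$ewbr))
})

test_that("EWB and EWBr are invariant to translation and uniform rescaling", {
  set.seed(109)
  agent <- agent_params(0.2, 0.9, -15, motor_sd_mm = 3,
                        repro_model = "subjective_line", repro_sd_mm = 3)
  b <- simulate_bisection(agent, independent_pairs(40))
  r <- simulate_reproduction(agent, b)
  ewb0 <- fit_bisection_weightings(b)$ewb
  ewbr0 <- fit_reproduction_weightings(r)$ewbr

  shift <- function(df, cols, by) {
    df[cols] <- lapply(df[cols], `+`, by); df
  }
  scale_cols <- function(df, cols, by) {
    df[cols] <- lapply(df[cols], `*`, by); df
  }
  bcols <- c("left_mm", "right_mm", "response_mm")
  rcols <- c("left_mm", "right_mm", "bisection_response_mm", "reproduced_mm")

  expect_equal(fit_bisection_weightings(shift(b, bcols, 83))$ewb, ewb0,
               tolerance = 1e-9)
  expect_equal(fit_bisection_weightings(scale_cols(b, bcols, 2.5))$ewb, ewb0,
               tolerance = 1e-9)
  expect_equal(fit_reproduction_weightings(shift(r, rcols, -42))$ewbr, ewbr0,
               tolerance = 1e-9)
  expect_equal(fit_reproduction_weightings(scale_cols(r, rcols, 0.4))$ewbr,
               ewbr0, tolerance = 1e-9)
})

test_that("estimated EWB is strictly increasing in the right weighting", {
  set.seed(110)
  pairs <- independent_pairs(25)
  ewbs <- vapply(seq(0.5, 1.1, by = 0.15), function(wr) {
    fit_bisection_weightings(linear_trials(pairs, 0.2, wr, -5))$ewb
  }, numeric(1))
  expect_true(all(diff(ewbs) > 0))
})

test_that("EWB and the DBE-length slope always share a sign", {
  set.seed(111)
  for (i in 1:10) {
    w <- runif(2, 0, 1.2)
    b <- simulate_bisection(agent_params(w[1], w[2], runif(1, -20, 20),
                                         motor_sd_mm = 2), length_pairs(reps = 10))
    fit <- ewb_from_length_slope(b)
    expect_equal(sign(fit$ewb), sign(fit$slope_dbe_per_mm))
  }
})
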
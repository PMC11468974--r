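test_that("baseline-incidence calibration solves the prevalence-weighted equation", {
  # reference-level identity and no-effect cases
  expect_equal(calibrate_baseline_incidence(0.05, c(1, 0, 0), c(1, 0.8, 0.7)), 0.05)
  expect_equal(calibrate_baseline_incidence(0.05, c(0.2, 0.5, 0.3), c(1, 1, 1)), 0.05)
  # one-unknown linear equation solved by hand: 0.01 / (0.2 + 0.3*0.8 + 0.5*0.7)
  expect_equal(calibrate_baseline_incidence(0.01, c(0.2, 0.3, 0.5), c(1, 0.8, 0.7)),
               0.01 / 0.79, tolerance = 1e-12)
  expect_error(calibrate_baseline_incidence(0.01, c(0, 0, 1), c(1, 1, 0)),
               "infeasible")
  expect_error(calibrate_baseline_incidence(0.01, c(0.2, 0.3, 0.5), c(0.9, 1, 1)),
               "inactive")
})

test_that("calibration round-trip recovers the observed rate", {
  set.seed(5)
  for (i in 1:50) {
    prev <- as.numeric(rmultinom(1, 1000, runif(3))) / 1000
    rr <- c(1, runif(2, 0.3, 1.5))
    obs <- runif(1, 0, 0.2)
    i0 <- calibrate_baseline_incidence(obs, prev, rr)
    expect_equal(sum(prev * rr * i0), obs, tolerance = 1e-12)
  }
})

test_that("rate-to-probability conversion is the standard actuarial map", {
  expect_equal(rate_to_probability(0, 1), 0)
  expect_equal(rate_to_probability(0.02 * 0.8, 1), 1 - exp(-0.016), tolerance = 1e-12)
  expect_equal(rate_to_probability(1e9, 1), 1)
  expect_error(rate_to_probability(-0.1), ">= 0")
  # monotone and bounded
  r <- seq(0, 5, by = 0.1)
  p <- rate_to_probability(r)
  expect_true(all(diff(p) > 0) && all(p >= 0 & p < 1))
})

test_that("zero compliance makes the intervention matrix equal the control matrix", {
  p <- set_parameter(full_params(), "compliance", 0)
  for (b in c(1, 8, 15)) {
    Mi <- build_transition_matrix(p, b, "intervention")
    Mc <- build_transition_matrix(p, b, "control")
    expect_equal(unclass(Mi), unclass(Mc), ignore_attr = TRUE)
  }
})

test_that("a static cohort (zero rates, identity PA shift) has an identity matrix", {
  p <- make_manual_params()
  M <- build_transition_matrix(p, 1, "intervention")
  expect_equal(unname(unclass(M)), diag(12), ignore_attr = TRUE, tolerance = 1e-15)
})

test_that("matrix entries match a hand-computed composition (PA shift, onset, death)", {
  S <- matrix(c(0.7, 0.2, 0.1,
                0.1, 0.8, 0.1,
                0.0, 0.05, 0.95), 3, 3, byrow = TRUE)
  rr_inc <- rbind(diabetes = c(1, 0.8, 0.6), hypertension = c(1, 0.85, 0.7),
                  diabetes_cvd = c(1, 0.9, 0.75), hypertension_stroke = c(1, 0.9, 0.8))
  rr_mort <- rbind(healthy = c(1, 0.9, 0.8), diabetes = c(1, 0.92, 0.85),
                   hypertension = c(1, 0.91, 0.82))
  p <- make_manual_params(mortality = 0.01, inc_d = 0.02, inc_h = 0.03,
                          comp_d = 0.05, comp_h = 0.04,
                          rr_inc = rr_inc, rr_mort = rr_mort,
                          comp_mort = c(diabetes_cvd = 2, hypertension_stroke = 3),
                          pa_shift_int = S, compliance = 1)
  M <- build_transition_matrix(p, 1, "intervention")

  # with all baseline PA prevalence on inactive, calibrated i0 = observed rate
  pd <- function(k) unname(1 - exp(-0.02 * rr_inc["diabetes", k]))
  ph <- function(k) unname(1 - exp(-0.03 * rr_inc["hypertension", k]))
  pc <- function(k) unname(1 - exp(-0.05 * rr_inc["diabetes_cvd", k]))
  ps <- function(k) unname(1 - exp(-0.04 * rr_inc["hypertension_stroke", k]))
  die_h <- function(k) unname(1 - exp(-0.01 * rr_mort["healthy", k]))
  die_d <- function(k) unname(1 - exp(-0.01 * rr_mort["diabetes", k]))
  die_cvd <- 1 - exp(-0.01 * 2)
  die_stk <- 1 - exp(-0.01 * 3)

  # healthy_inactive -> diabetes_low: shift to low, onset at low, survive
  expect_equal(M["healthy_inactive", "diabetes_low"],
               S[1, 2] * pd(2) * (1 - die_d(2)), tolerance = 1e-14)
  # healthy_inactive -> healthy_mod_high: shift up, no onset, survive
  expect_equal(M["healthy_inactive", "healthy_mod_high"],
               S[1, 3] * (1 - pd(3) - ph(3)) * (1 - die_h(3)), tolerance = 1e-14)
  # diabetes_inactive -> diabetes_cvd: any PA shift, complication onset, survive
  expect_equal(M["diabetes_inactive", "diabetes_cvd"],
               sum(S[1, ] * vapply(1:3, pc, numeric(1))) * (1 - die_cvd),
               tolerance = 1e-14)
  # complication states: self-loop and death only, chronic
  expect_equal(M["diabetes_cvd", "diabetes_cvd"], 1 - die_cvd, tolerance = 1e-14)
  expect_equal(M["diabetes_cvd", "dead"], die_cvd, tolerance = 1e-14)
  expect_equal(sum(M["hypertension_stroke", c("hypertension_stroke", "dead")]), 1,
               tolerance = 1e-14)
  expect_equal(M["hypertension_stroke", "dead"], die_stk, tolerance = 1e-14)
  # dead is absorbing
  expect_equal(unname(M["dead", ]), c(rep(0, 11), 1))
  expect_equal(unname(rowSums(M)), rep(1, 12), tolerance = 1e-12)
})

test_that("transition matrices are row-stochastic for 1000 random valid parameter sets", {
  worst <- 0
  for (s in 1:1000) {
    p <- generate_parameter_set(s, "toy")
    b <- 1L + (s %% nrow(p$age_bands))
    sit <- if (s %% 2 == 0) "intervention" else "control"
    M <- build_transition_matrix(p, b, sit)
    worst <- max(worst, max(abs(rowSums(M) - 1)))
    if (any(M < 0 | M > 1)) fail(paste("entry out of [0,1] at seed", s))
  }
  expect_lt(worst, 1e-12)
})

test_that("onset probability is monotone in the corresponding relative risk", {
  base <- full_params()
  grid <- seq(0.3, 1, by = 0.1)
  prev_p <- -Inf
  for (v in grid) {
    p <- set_parameter(base, "rr_incidence.diabetes.mod_high", v)
    M <- build_transition_matrix(p, 8, "control")
    onset <- M["healthy_mod_high", "diabetes_mod_high"]
    expect_gte(onset, prev_p)
    prev_p <- onset
  }
})

test_that("inconsistent onset probabilities raise an error instead of clipping", {
  p <- make_manual_params(inc_d = 30, inc_h = 30)
  expect_error(build_transition_matrix(p, 1, "control"), "inconsistency")
})

test_that("transition matrices export to CSV and re-parse", {
  M <- build_transition_matrix(toy_params(), 1, "intervention")
  path <- withr::local_tempfile(fileext = ".csv")
  write_transition_csv(M, path)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(back$state, state_names())
  expect_equal(as.matrix(back[, -1]), unclass(M), ignore_attr = TRUE, tolerance = 1e-12)
})
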
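# Shared fixtures, all built in code at test time.

.fixture_env <- new.env(parent = emptyenv())

toy_params <- function(seed = 101) {
  key <- paste0("toy", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_parameter_set(seed, "toy")
  .fixture_env[[key]]
}

full_params <- function(seed = 1) {
  key <- paste0("full", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_parameter_set(seed, "full")
  .fixture_env[[key]]
}

# minimal single-band parameter set with hand-settable rates, for exact
# arithmetic oracles
make_manual_params <- function(mortality = 0, inc_d = 0, inc_h = 0,
                               comp_d = 0, comp_h = 0,
                               rr_inc = NULL, rr_mort = NULL,
                               comp_mort = c(diabetes_cvd = 1, hypertension_stroke = 1),
                               pa_prev = NULL, prev = c(1, 0, 0),
                               pa_shift_int = diag(3), pa_shift_ctrl = diag(3),
                               compliance = 0, program_cost = 0,
                               utilities = NULL, costs = NULL,
                               horizon = 10L, discount = 0.03,
                               n_registered = 1000) {
  lv <- pa_levels()
  if (is.null(rr_inc)) {
    rr_inc <- matrix(1, 4, 3, dimnames = list(
      c("diabetes", "hypertension", "diabetes_cvd", "hypertension_stroke"), lv))
  }
  if (is.null(rr_mort))
    rr_mort <- matrix(1, 3, 3, dimnames = list(
      c("healthy", "diabetes", "hypertension"), lv))
  if (is.null(pa_prev)) {
    pa_prev <- matrix(rep(c(1, 0, 0), 3), 3, 3, byrow = TRUE,
                      dimnames = list(c("healthy", "diabetes", "hypertension"), lv))
  }
  if (is.null(utilities))
    utilities <- list(base = c(healthy = 1, diabetes = 1, hypertension = 1,
                               diabetes_cvd = 1, hypertension_stroke = 1),
                      pa_delta = c(0, 0, 0))
  if (is.null(costs))
    costs <- list(inpatient = c(diabetes = 0, hypertension = 0,
                                diabetes_cvd = 0, hypertension_stroke = 0),
                  outpatient = c(diabetes = 0, hypertension = 0),
                  inpatient_proportion = c(diabetes = 0, hypertension = 0),
                  pa_multiplier = c(1, 1, 1))
  age_bands <- data.frame(
    band = "17-plus", age_lo = 17, age_hi = 120, fraction = 1,
    mortality = mortality, incidence_diabetes = inc_d,
    incidence_hypertension = inc_h, complication_diabetes_cvd = comp_d,
    complication_hypertension_stroke = comp_h,
    prev_healthy = prev[1], prev_diabetes = prev[2], prev_hypertension = prev[3],
    stringsAsFactors = FALSE
  )
  parameter_set(
    age_bands = age_bands, pa_prevalence = pa_prev, rr_incidence = rr_inc,
    rr_mortality = rr_mort, complication_mortality = comp_mort,
    utilities = utilities, costs = costs,
    direct_indirect_ratio = c(diabetes = 1, hypertension = 1),
    intervention_pa_shift = pa_shift_int, control_pa_shift = pa_shift_ctrl,
    program_cost_annual = program_cost, compliance = compliance,
    n_registered = n_registered, incidence_scale = 1,
    discount_rate = discount, horizon_years = horizon
  )
}

# distributions table where every parameter is degenerate at its base value
degenerate_distributions <- function(params) {
  d <- params$distributions
  for (i in seq_len(nrow(d))) {
    d$family[i] <- "degenerate"
    d$p1[i] <- get_parameter(params, d$name[i])
    d$p2[i] <- NA_real_
  }
  d
}

# closed-form discounted annuity, the geometric-series oracle
annuity <- function(r, T) if (r == 0) T else (1 - (1 + r)^(-T)) / r
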
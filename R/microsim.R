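# Individual-level Monte Carlo microsimulation. Used as an independent oracle
# for the cohort engine: identical state space, identical transition matrices,
# identical within-cycle event order (PA shift, onset, death are already
# composed into the one-cycle matrices), but each individual's path is
# sampled, so totals carry Monte Carlo standard errors.

#' Microsimulation oracle
#'
#' Samples `n_individuals` initial (band, state) positions from the same
#' distribution the cohort engine uses, walks each individual through the
#' one-cycle transition matrices, and accumulates half-cycle-corrected,
#' discounted QALYs and costs per individual. Estimates are scaled to a cohort
#' of size `n_cohort` (default `n_individuals`).
#'
#' @param params A `parameter_set`.
#' @param n_individuals Number of simulated individuals.
#' @param seed Integer seed.
#' @param situation `"intervention"` or `"control"`.
#' @param n_cohort Cohort size the estimates are scaled to.
#' @return List with `estimate` (an `outcome_summary`), `se` (standard errors
#'   for `qalys`, `direct_cost`, `indirect_cost`), `occupancy` (counts per
#'   state at each cycle boundary, summed over bands) and `n_individuals`.
#' @export
microsim_oracle <- function(params, n_individuals = 10000L, seed = 1L,
                            situation = c("intervention", "control"),
                            n_cohort = NULL) {
  situation <- match.arg(situation)
  if (is.null(n_cohort)) n_cohort <- n_individuals
  set.seed(as.integer(seed) %% 2147483647L)
  nb <- n_bands(params)
  T_ <- params$horizon_years
  idx <- .state_idx

  # initial joint distribution over (band, state), matching initialize_cohort
  init <- initialize_cohort(params, 1)
  probs <- as.numeric(t(init)) # band-major, state within band
  cell <- sample.int(nb * 12L, n_individuals, replace = TRUE, prob = probs)
  band0 <- (cell - 1L) %/% 12L + 1L
  state <- (cell - 1L) %% 12L + 1L

  mats <- lapply(seq_len(nb), function(b) build_transition_matrix(params, b, situation))
  rep_age <- band_rep_age(params)
  u <- state_utilities(params)
  cc <- state_costs(params)
  disc <- discount_factors(params)

  qaly_i <- direct_i <- indirect_i <- numeric(n_individuals)
  diab_i <- hyp_i <- comp_i <- dead_i <- logical(n_individuals)
  occupancy <- matrix(0L, T_ + 1L, 12L, dimnames = list(NULL, state_names()))
  occupancy[1L, ] <- tabulate(state, 12L)
  had_disease <- state %in% c(idx$diabetes, idx$hypertension)

  for (t in seq_len(T_)) {
    bands_now <- age_to_band(params, rep_age[band0] + (t - 1L))
    new_state <- state
    for (b in unique(bands_now)) {
      M <- mats[[b]]
      for (s in unique(state[bands_now == b])) {
        sel <- which(bands_now == b & state == s)
        if (s == idx$dead) next
        new_state[sel] <- sample.int(12L, length(sel), replace = TRUE, prob = M[s, ])
      }
    }
    # incident flags (first entry into each state family)
    diab_i <- diab_i | (!state %in% c(idx$diabetes, idx$diabetes_cvd) &
                          new_state %in% idx$diabetes)
    hyp_i <- hyp_i | (!state %in% c(idx$hypertension, idx$hypertension_stroke) &
                        new_state %in% idx$hypertension)
    comp_i <- comp_i | (!state %in% c(idx$diabetes_cvd, idx$hypertension_stroke) &
                          new_state %in% c(idx$diabetes_cvd, idx$hypertension_stroke))
    dead_i <- dead_i | (new_state == idx$dead & state != idx$dead)

    hw <- disc[t] / 2
    qaly_i <- qaly_i + hw * (u[state] + u[new_state])
    direct_i <- direct_i + hw * (cc$direct[state] + cc$direct[new_state])
    indirect_i <- indirect_i + hw * (cc$indirect[state] + cc$indirect[new_state])
    state <- new_state
    occupancy[t + 1L, ] <- tabulate(state, 12L)
  }

  scale <- n_cohort / n_individuals
  program <- if (situation == "intervention") sum(disc * params$program_cost_annual) else 0
  est <- structure(list(
    qalys = sum(qaly_i) * scale,
    direct_cost = sum(direct_i) * scale,
    indirect_cost = sum(indirect_i) * scale,
    program_cost = program,
    cum_diabetes = sum(diab_i) * scale,
    cum_hypertension = sum(hyp_i) * scale,
    cum_complications = sum(comp_i) * scale,
    cum_deaths = sum(dead_i) * scale,
    n = n_cohort, situation = situation
  ), class = "outcome_summary")
  se <- c(
    qalys = stats::sd(qaly_i) / sqrt(n_individuals) * n_cohort,
    direct_cost = stats::sd(direct_i) / sqrt(n_individuals) * n_cohort,
    indirect_cost = stats::sd(indirect_i) / sqrt(n_individuals) * n_cohort
  )
  list(estimate = est, se = se, occupancy = occupancy,
       n_individuals = n_individuals)
}
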
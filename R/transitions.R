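# Transition-matrix construction. Within a cycle events are composed in a
# fixed order: (1) PA-level shift, (2) disease / complication onset,
# (3) death. Relative risks act multiplicatively on the rate scale and rates
# are converted to one-cycle probabilities with 1 - exp(-rate * cycle), which
# keeps probabilities in [0, 1) for any relative risk.

#' Calibrate a baseline (inactive-reference) rate from a population average
#'
#' Given a population-average event rate observed over a population whose PA
#' levels are distributed as `pa_prevalence`, and relative risks `rr` with
#' `rr[inactive] = 1`, returns the inactive-level rate `i0` such that the
#' prevalence-weighted average of `rr * i0` recovers the observed rate. The
#' per-level rate is then `rr[k] * i0`.
#'
#' @param observed_rate Population-average rate (events/person-year), `>= 0`.
#' @param pa_prevalence Length-3 PA prevalence, sums to 1.
#' @param rr Length-3 relative risks, reference first, `rr[1] = 1`.
#' @return The baseline inactive-level rate.
#' @export
calibrate_baseline_incidence <- function(observed_rate, pa_prevalence, rr) {
  if (observed_rate < 0) stop("observed_rate must be >= 0", call. = FALSE)
  if (abs(sum(pa_prevalence) - 1) > 1e-9)
    stop("pa_prevalence must sum to 1", call. = FALSE)
  if (rr[1] != 1) stop("rr[inactive] must be exactly 1", call. = FALSE)
  denom <- sum(pa_prevalence * rr)
  if (denom <= 0)
    stop("calibration infeasible: all prevalence mass on zero-risk levels", call. = FALSE)
  observed_rate / denom
}

#' Convert an annual rate to a one-cycle transition probability
#'
#' Standard actuarial conversion `1 - exp(-rate * cycle)`. Relative-risk
#' adjustments must be applied on the rate scale before conversion.
#'
#' @param rate Event rate (events/person-year), `>= 0`.
#' @param cycle Cycle length in years, `> 0`.
#' @return Probability in `[0, 1)`.
#' @export
rate_to_probability <- function(rate, cycle = 1) {
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  if (cycle <= 0) stop("cycle must be > 0", call. = FALSE)
  1 - exp(-rate * cycle)
}

# calibrated inactive-reference rates for one age band (incidence_scale applied
# to the observed population-average rates before calibration)
calibrated_incidence <- function(params, band) {
  ab <- params$age_bands[band, ]
  s <- params$incidence_scale
  pp <- params$pa_prevalence
  ri <- params$rr_incidence
  list(
    diabetes = calibrate_baseline_incidence(s * ab$incidence_diabetes,
                                            pp["healthy", ], ri["diabetes", ]),
    hypertension = calibrate_baseline_incidence(s * ab$incidence_hypertension,
                                                pp["healthy", ], ri["hypertension", ]),
    diabetes_cvd = calibrate_baseline_incidence(s * ab$complication_diabetes_cvd,
                                                pp["diabetes", ], ri["diabetes_cvd", ]),
    hypertension_stroke = calibrate_baseline_incidence(s * ab$complication_hypertension_stroke,
                                                       pp["hypertension", ], ri["hypertension_stroke", ])
  )
}

# effective annual PA-shift matrix for a situation: the compliant fraction of
# the intervention cohort follows the intervention shift, the rest the control
# (secular) shift
effective_pa_shift <- function(params, situation) {
  if (situation == "intervention") {
    params$compliance * params$intervention_pa_shift +
      (1 - params$compliance) * params$control_pa_shift
  } else {
    params$control_pa_shift
  }
}

#' Build the one-cycle transition matrix for an age band
#'
#' Composes, in order: PA-level shift within each PA-carrying group, disease
#' onset from healthy and complication onset from uncomplicated disease
#' (calibrated incidence times the PA-level relative risk, rate scale), and
#' death (all-cause mortality times the mortality relative risk). `dead` is
#' absorbing; complication states admit only self-loop and death.
#'
#' @param params A `parameter_set`.
#' @param age_band Band index (row of `params$age_bands`).
#' @param situation `"intervention"` or `"control"`.
#' @return A 12x12 row-stochastic matrix with state-name dimnames; the three
#'   composed stage matrices are attached as attribute `"stages"`.
#' @export
build_transition_matrix <- function(params, age_band,
                                    situation = c("intervention", "control")) {
  situation <- match.arg(situation)
  nS <- 12L
  idx <- .state_idx
  cyc <- params$cycle_length

  # stage 1: PA shift within each PA-carrying block
  S <- effective_pa_shift(params, situation)
  P1 <- diag(nS)
  for (block in idx$pa_blocks) P1[block, block] <- S

  # stage 2: disease and complication onset
  P2 <- diag(nS)
  inc <- calibrated_incidence(params, age_band)
  ri <- params$rr_incidence
  for (k in 1:3) {
    pd <- rate_to_probability(inc$diabetes * ri["diabetes", k], cyc)
    ph <- rate_to_probability(inc$hypertension * ri["hypertension", k], cyc)
    if (pd + ph > 1)
      stop("parameter inconsistency: onset probabilities from healthy (",
           PA_LEVELS[k], ") sum to ", signif(pd + ph, 4), " > 1", call. = FALSE)
    h <- idx$healthy[k]
    P2[h, h] <- 1 - pd - ph
    P2[h, idx$diabetes[k]] <- pd
    P2[h, idx$hypertension[k]] <- ph

    pc <- rate_to_probability(inc$diabetes_cvd * ri["diabetes_cvd", k], cyc)
    d <- idx$diabetes[k]
    P2[d, d] <- 1 - pc
    P2[d, idx$diabetes_cvd] <- pc

    ps <- rate_to_probability(inc$hypertension_stroke * ri["hypertension_stroke", k], cyc)
    hh <- idx$hypertension[k]
    P2[hh, hh] <- 1 - ps
    P2[hh, idx$hypertension_stroke] <- ps
  }

  # stage 3: death
  m <- params$age_bands$mortality[age_band]
  rrm <- params$rr_mortality
  pdie <- numeric(nS)
  for (g in seq_along(PA_GROUPS))
    pdie[idx$pa_blocks[[g]]] <- rate_to_probability(m * rrm[PA_GROUPS[g], ], cyc)
  pdie[idx$diabetes_cvd] <- rate_to_probability(m * params$complication_mortality["diabetes_cvd"], cyc)
  pdie[idx$hypertension_stroke] <- rate_to_probability(m * params$complication_mortality["hypertension_stroke"], cyc)
  P3 <- diag(1 - pdie)
  P3[, idx$dead] <- P3[, idx$dead] + pdie
  P3[idx$dead, ] <- 0
  P3[idx$dead, idx$dead] <- 1

  M <- P1 %*% P2 %*% P3
  dimnames(M) <- list(state_names(), state_names())
  attr(M, "stages") <- list(pa = P1, onset = P2, death = P3)
  M
}

#' Write a transition matrix to CSV
#'
#' @param M Matrix from [build_transition_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_transition_csv <- function(M, path) {
  df <- as.data.frame(M)
  df <- cbind(state = rownames(M), df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
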
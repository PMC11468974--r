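# Closed-cohort Markov engine: occupancy is tracked per (initial age band,
# state); each band's sub-cohort ages deterministically one year per cycle and
# uses the transition matrix of the band its current age falls in.

#' Estimate the closed-cohort size
#'
#' Cohort size is the number of registrants scaled by the fraction who complete
#' (keep syncing through) the program.
#'
#' @param n_registered Registered participants.
#' @param completion_fraction Fraction in `[0, 1]`.
#' @return `n_registered * completion_fraction`.
#' @examples
#' estimate_cohort_size(1.7e6, 0.385) # 654,500
#' @export
estimate_cohort_size <- function(n_registered, completion_fraction) {
  if (completion_fraction < 0 || completion_fraction > 1)
    stop("completion_fraction must lie in [0, 1]", call. = FALSE)
  if (n_registered < 0) stop("n_registered must be >= 0", call. = FALSE)
  n_registered * completion_fraction
}

#' Initialise cohort occupancy
#'
#' Distributes `n` persons over the 9 PA-carrying living states within each age
#' band as band fraction x disease prevalence x PA prevalence. Complication
#' states and `dead` start empty.
#'
#' @param params A `parameter_set`.
#' @param n Cohort size (persons).
#' @return A `n_bands x 12` matrix of persons; rows are age bands, columns the
#'   canonical states.
#' @export
initialize_cohort <- function(params, n) {
  if (n <= 0) stop("cohort size must be > 0", call. = FALSE)
  nb <- n_bands(params)
  occ <- matrix(0, nb, 12L, dimnames = list(params$age_bands$band, state_names()))
  ab <- params$age_bands
  pp <- params$pa_prevalence
  prev <- cbind(ab$prev_healthy, ab$prev_diabetes, ab$prev_hypertension)
  for (b in seq_len(nb)) {
    for (g in seq_along(PA_GROUPS)) {
      occ[b, .state_idx$pa_blocks[[g]]] <- n * ab$fraction[b] * prev[b, g] * pp[g, ]
    }
  }
  occ
}

#' Run the cohort Markov trace
#'
#' Propagates occupancy over `horizon_years` one-year cycles. Incident counts
#' are the probability-mass flows into the diabetes, hypertension, complication
#' and dead states during each cycle, read off the staged (PA shift, onset,
#' death) decomposition of the transition matrices.
#'
#' @param initial Occupancy matrix from [initialize_cohort()].
#' @param params A `parameter_set`.
#' @param situation `"intervention"` or `"control"`.
#' @return A `cohort_trace`: list with `occupancy` (array `[T+1, bands, 12]`),
#'   `incident` (data frame, one row per cycle: `new_diabetes`,
#'   `new_hypertension`, `new_complications`, `deaths`), `n`, `situation`.
#' @export
run_markov_trace <- function(initial, params, situation = c("intervention", "control")) {
  situation <- match.arg(situation)
  nb <- n_bands(params)
  if (!is.matrix(initial) || nrow(initial) != nb || ncol(initial) != 12L)
    stop("initial occupancy must be a ", nb, " x 12 matrix", call. = FALSE)
  T_ <- params$horizon_years
  idx <- .state_idx

  mats <- lapply(seq_len(nb), function(b) build_transition_matrix(params, b, situation))
  rep_age <- band_rep_age(params)

  occ <- array(0, dim = c(T_ + 1L, nb, 12L),
               dimnames = list(NULL, params$age_bands$band, state_names()))
  occ[1L, , ] <- initial
  incident <- data.frame(cycle = seq_len(T_), new_diabetes = 0, new_hypertension = 0,
                         new_complications = 0, deaths = 0)

  for (t in seq_len(T_)) {
    bands_now <- age_to_band(params, rep_age + (t - 1L))
    for (b in seq_len(nb)) {
      o0 <- occ[t, b, ]
      st <- attr(mats[[bands_now[b]]], "stages")
      o1 <- as.numeric(o0 %*% st$pa)
      P2 <- st$onset
      new_d <- sum(o1[idx$healthy] * P2[cbind(idx$healthy, idx$diabetes)])
      new_h <- sum(o1[idx$healthy] * P2[cbind(idx$healthy, idx$hypertension)])
      new_c <- sum(o1[idx$diabetes] * P2[idx$diabetes, idx$diabetes_cvd]) +
        sum(o1[idx$hypertension] * P2[idx$hypertension, idx$hypertension_stroke])
      o2 <- as.numeric(o1 %*% P2)
      o3 <- as.numeric(o2 %*% st$death)
      incident$new_diabetes[t] <- incident$new_diabetes[t] + new_d
      incident$new_hypertension[t] <- incident$new_hypertension[t] + new_h
      incident$new_complications[t] <- incident$new_complications[t] + new_c
      incident$deaths[t] <- incident$deaths[t] + (o3[idx$dead] - o0[idx$dead])
      occ[t + 1L, b, ] <- o3
    }
  }
  structure(list(occupancy = occ, incident = incident, n = sum(initial),
                 situation = situation),
            class = "cohort_trace")
}

#' Half-cycle-corrected person-years for one cycle
#'
#' Trapezoidal person-years: the arithmetic mean of state occupancy at the two
#' bounding cycle boundaries.
#'
#' @param occ_start,occ_end Occupancy vectors (or matrices) at the cycle start
#'   and end.
#' @return Person-years, same shape as the inputs.
#' @export
half_cycle_effective <- function(occ_start, occ_end) (occ_start + occ_end) / 2

# per-state annual utility / direct cost / indirect cost vectors (length 12)
state_utilities <- function(params) {
  ub <- params$utilities$base
  pd <- params$utilities$pa_delta
  u <- numeric(12L)
  for (g in seq_along(PA_GROUPS))
    u[.state_idx$pa_blocks[[g]]] <- pmin(1, ub[PA_GROUPS[g]] + pd)
  u[.state_idx$diabetes_cvd] <- ub["diabetes_cvd"]
  u[.state_idx$hypertension_stroke] <- ub["hypertension_stroke"]
  u[.state_idx$dead] <- 0
  u
}

state_costs <- function(params) {
  cst <- params$costs
  direct <- numeric(12L)
  for (dis in c("diabetes", "hypertension")) {
    annual <- cst$inpatient_proportion[dis] * cst$inpatient[dis] +
      (1 - cst$inpatient_proportion[dis]) * cst$outpatient[dis]
    direct[.state_idx$pa_blocks[[dis]]] <- annual * cst$pa_multiplier
  }
  # complications are treated as all-inpatient; PA cost differentiation does
  # not apply (complication states carry no PA level)
  direct[.state_idx$diabetes_cvd] <- cst$inpatient["diabetes_cvd"]
  direct[.state_idx$hypertension_stroke] <- cst$inpatient["hypertension_stroke"]
  ratio <- params$direct_indirect_ratio
  indirect <- numeric(12L)
  grp <- .state_group()
  for (dis in c("diabetes", "hypertension"))
    indirect[grp == dis] <- direct[grp == dis] / ratio[dis]
  list(direct = direct, indirect = indirect)
}

discount_factors <- function(params) {
  t_ <- seq_len(params$horizon_years)
  expo <- if (params$discount_timing == "mid") t_ - 0.5 else t_
  (1 + params$discount_rate)^(-expo)
}

#' Accumulate discounted outcomes from a cohort trace
#'
#' For each cycle, half-cycle-corrected person-years per state are priced with
#' per-state annual utilities and costs and discounted. Direct cost per
#' uncomplicated disease state is `inpatient_proportion * inpatient +
#' (1 - inpatient_proportion) * outpatient`; complication states are
#' all-inpatient. Indirect cost is direct cost divided by the disease's
#' direct-to-indirect ratio. Program cost accrues (undiscounted
#' `program_cost_annual` per cycle, then discounted) only in the intervention
#' situation and is reported separately from health-care cost.
#'
#' @param trace A `cohort_trace`.
#' @param params A `parameter_set`.
#' @return An `outcome_summary`: list with `qalys`, `direct_cost`,
#'   `indirect_cost`, `program_cost`, `cum_diabetes`, `cum_hypertension`,
#'   `cum_complications`, `cum_deaths`, `n`, `situation`.
#' @export
accumulate_outcomes <- function(trace, params) {
  T_ <- params$horizon_years
  u <- state_utilities(params)
  cc <- state_costs(params)
  disc <- discount_factors(params)

  qalys <- direct <- indirect <- 0
  for (t in seq_len(T_)) {
    o0 <- band_total(trace$occupancy, t)
    o1 <- band_total(trace$occupancy, t + 1L)
    py <- half_cycle_effective(o0, o1)
    qalys <- qalys + disc[t] * sum(py * u)
    direct <- direct + disc[t] * sum(py * cc$direct)
    indirect <- indirect + disc[t] * sum(py * cc$indirect)
  }
  program <- if (trace$situation == "intervention")
    sum(disc * params$program_cost_annual) else 0

  structure(list(
    qalys = qalys, direct_cost = direct, indirect_cost = indirect,
    program_cost = program,
    cum_diabetes = sum(trace$incident$new_diabetes),
    cum_hypertension = sum(trace$incident$new_hypertension),
    cum_complications = sum(trace$incident$new_complications),
    cum_deaths = sum(trace$incident$deaths),
    n = trace$n, situation = trace$situation
  ), class = "outcome_summary")
}

# occupancy summed over bands at boundary t -> length-12 vector
band_total <- function(occupancy, t) {
  m <- occupancy[t, , , drop = FALSE]
  dim(m) <- dim(occupancy)[2:3]
  colSums(m)
}

#' Projected prevalence at a cycle boundary
#'
#' Normalised occupancy over the living states: disease-group shares (the
#' complication states count towards their parent disease) and PA-level shares
#' among the PA-carrying living states.
#'
#' @param trace A `cohort_trace`.
#' @param year Cycle boundary, `0..horizon`.
#' @return List with `disease` (healthy/diabetes/hypertension fractions) and
#'   `pa` (inactive/low/mod_high fractions).
#' @export
project_prevalence <- function(trace, year) {
  T_ <- dim(trace$occupancy)[1] - 1L
  if (year < 0 || year > T_) stop("year must lie in 0..", T_, call. = FALSE)
  o <- band_total(trace$occupancy, year + 1L)
  idx <- .state_idx
  living <- sum(o[idx$living])
  if (living <= 0) stop("prevalence undefined: no survivors at year ", year, call. = FALSE)
  disease <- c(
    healthy = sum(o[idx$healthy]),
    diabetes = sum(o[idx$diabetes]) + o[idx$diabetes_cvd],
    hypertension = sum(o[idx$hypertension]) + o[idx$hypertension_stroke]
  ) / living
  pa_states <- sum(o[1:9])
  pa <- setNames(numeric(3), PA_LEVELS)
  if (pa_states > 0)
    for (k in 1:3) pa[k] <- sum(o[c(k, k + 3L, k + 6L)]) / pa_states
  list(disease = disease, pa = pa)
}

#' Run one situation end-to-end
#'
#' Initialises the cohort, runs the trace and accumulates outcomes.
#'
#' @param params A `parameter_set`.
#' @param situation `"intervention"` or `"control"`.
#' @param n Cohort size; default `n_registered * compliance`.
#' @return An `outcome_summary` with the trace attached as attribute `"trace"`.
#' @export
run_model <- function(params, situation = c("intervention", "control"), n = NULL) {
  situation <- match.arg(situation)
  if (is.null(n)) n <- estimate_cohort_size(params$n_registered, params$compliance)
  trace <- run_markov_trace(initialize_cohort(params, n), params, situation)
  out <- accumulate_outcomes(trace, params)
  attr(out, "trace") <- trace
  out
}

#' Trace occupancy as a data frame
#'
#' @param trace A `cohort_trace`.
#' @return Data frame, one row per cycle boundary, one column per state
#'   (summed over age bands), plus the per-cycle incident counts merged in.
#' @export
trace_to_df <- function(trace) {
  T1 <- dim(trace$occupancy)[1]
  tot <- t(vapply(seq_len(T1), function(t) band_total(trace$occupancy, t), numeric(12)))
  colnames(tot) <- state_names()
  df <- data.frame(boundary = 0:(T1 - 1L), tot, check.names = FALSE)
  inc <- rbind(data.frame(cycle = 0, new_diabetes = NA, new_hypertension = NA,
                          new_complications = NA, deaths = NA),
               trace$incident)
  cbind(df, inc[, -1])
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat("<outcome_summary> situation:", x$situation, " cohort:",
      format(round(x$n), big.mark = ","), "\n")
  cat(sprintf("  QALYs %.1f | direct SGD %.0f | indirect SGD %.0f | program SGD %.0f\n",
              x$qalys, x$direct_cost, x$indirect_cost, x$program_cost))
  cat(sprintf("  incident: diabetes %.1f, hypertension %.1f, complications %.1f, deaths %.1f\n",
              x$cum_diabetes, x$cum_hypertension, x$cum_complications, x$cum_deaths))
  invisible(x)
}
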
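# ParameterSet: the complete instantiation of the model. Built either by the
# synthetic generator or by read_config(); validated eagerly with field-level
# messages. Age-varying quantities live in the age_bands data frame; scalar
# quantities addressed by dot-path names (see get_parameter / set_parameter)
# are the ones the uncertainty analyses vary.

.AGE_BAND_COLS <- c("band", "age_lo", "age_hi", "fraction", "mortality",
                    "incidence_diabetes", "incidence_hypertension",
                    "complication_diabetes_cvd", "complication_hypertension_stroke",
                    "prev_healthy", "prev_diabetes", "prev_hypertension")

#' Construct a parameter set
#'
#' Assembles and validates the full model parameterisation: demography,
#' epidemiology (age-specific incidence, complication incidence, mortality),
#' relative risks by physical-activity level, utilities, costs, program
#' economics and per-parameter uncertainty distributions.
#'
#' @param age_bands Data frame, one row per 5-year age band, with columns
#'   `band`, `age_lo`, `age_hi`, `fraction` (population share, sums to 1),
#'   `mortality` (annual all-cause rate), `incidence_diabetes`,
#'   `incidence_hypertension` (annual population-average onset rates),
#'   `complication_diabetes_cvd`, `complication_hypertension_stroke` (annual
#'   complication-onset rates from the uncomplicated disease states),
#'   `prev_healthy`, `prev_diabetes`, `prev_hypertension` (baseline disease
#'   prevalence, sums to 1 per band).
#' @param pa_prevalence 3x3 matrix (rows: healthy/diabetes/hypertension, cols:
#'   inactive/low/mod_high), baseline PA distribution within each disease
#'   group; rows sum to 1.
#' @param rr_incidence 4x3 matrix of onset relative risks (rows: diabetes,
#'   hypertension, diabetes_cvd, hypertension_stroke; cols: PA levels);
#'   `inactive` column is exactly 1.
#' @param rr_mortality 3x3 matrix of mortality relative risks for the living
#'   PA-carrying groups; `inactive` column is exactly 1.
#' @param complication_mortality Named length-2 vector of mortality multipliers
#'   for `diabetes_cvd` and `hypertension_stroke`.
#' @param utilities List with `base` (named utilities for healthy, diabetes,
#'   hypertension, diabetes_cvd, hypertension_stroke) and `pa_delta` (length-3
#'   additive PA adjustment, reference level first).
#' @param costs List with `inpatient` (named: diabetes, hypertension,
#'   diabetes_cvd, hypertension_stroke), `outpatient` (named: diabetes,
#'   hypertension), `inpatient_proportion` (named: diabetes, hypertension) and
#'   `pa_multiplier` (length-3, base case all 1).
#' @param direct_indirect_ratio Named length-2 vector (diabetes, hypertension):
#'   ratio of direct to indirect cost; indirect = direct / ratio.
#' @param intervention_pa_shift,control_pa_shift 3x3 row-stochastic annual PA
#'   transition matrices.
#' @param program_cost_annual Annual program cost, SGD.
#' @param compliance Fraction of registrants exposed to the intervention
#'   effect; also the completion fraction linking registrants to cohort size.
#' @param n_registered Registered participants (cohort size =
#'   `n_registered * compliance`).
#' @param incidence_scale Multiplier applied to all onset/complication rates
#'   (base 1).
#' @param discount_rate Per-annum discount rate (base 0.03).
#' @param horizon_years Model horizon in one-year cycles (base 10).
#' @param cycle_length Cycle length in years (fixed at 1).
#' @param wtp_grid Willingness-to-pay grid, SGD/QALY.
#' @param discount_timing `"end"` (discount factor (1+r)^-t for cycle t) or
#'   `"mid"` ((1+r)^-(t-1/2)).
#' @param distributions Data frame of [dist_spec()] rows, one per uncertain
#'   parameter.
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(age_bands, pa_prevalence, rr_incidence, rr_mortality,
                          complication_mortality, utilities, costs,
                          direct_indirect_ratio,
                          intervention_pa_shift, control_pa_shift,
                          program_cost_annual, compliance, n_registered,
                          incidence_scale = 1,
                          discount_rate = 0.03, horizon_years = 10L,
                          cycle_length = 1, wtp_grid = c(0, 5000, 10000),
                          discount_timing = c("end", "mid"),
                          distributions = empty_distributions()) {
  discount_timing <- match.arg(discount_timing)
  params <- structure(list(
    age_bands = age_bands,
    pa_prevalence = pa_prevalence,
    rr_incidence = rr_incidence,
    rr_mortality = rr_mortality,
    complication_mortality = complication_mortality,
    utilities = utilities,
    costs = costs,
    direct_indirect_ratio = direct_indirect_ratio,
    intervention_pa_shift = intervention_pa_shift,
    control_pa_shift = control_pa_shift,
    program_cost_annual = program_cost_annual,
    compliance = compliance,
    n_registered = n_registered,
    incidence_scale = incidence_scale,
    discount_rate = discount_rate,
    horizon_years = as.integer(round(horizon_years)),
    cycle_length = cycle_length,
    wtp_grid = wtp_grid,
    discount_timing = discount_timing,
    distributions = distributions
  ), class = "parameter_set")
  params <- normalize_parameter_set(params)
  validate_parameter_set(params)
  params
}

# canonical attribute layout so that generated and file-parsed sets compare
# equal: plain row names, PA-level dimnames on the shift matrices
normalize_parameter_set <- function(params) {
  rownames(params$age_bands) <- NULL
  rownames(params$distributions) <- NULL
  dimnames(params$intervention_pa_shift) <- list(PA_LEVELS, PA_LEVELS)
  dimnames(params$control_pa_shift) <- list(PA_LEVELS, PA_LEVELS)
  dimnames(params$pa_prevalence) <- list(PA_GROUPS, PA_LEVELS)
  params
}

empty_distributions <- function() {
  data.frame(name = character(), family = character(), p1 = numeric(),
             p2 = numeric(), range_rule = character(), stringsAsFactors = FALSE)
}

.fail <- function(field, msg) {
  stop("invalid parameter set: field '", field, "': ", msg, call. = FALSE)
}

#' Validate a parameter set
#'
#' Checks every structural invariant (stochastic rows, probabilities in
#' \[0,1\], reference relative risks exactly 1, utility ordering, positive
#' costs) and fails with a message naming the offending field.
#'
#' @param params A `parameter_set`.
#' @return The parameter set, invisibly, if valid.
#' @export
validate_parameter_set <- function(params) {
  ab <- params$age_bands
  if (!is.data.frame(ab)) .fail("age_bands", "must be a data frame")
  missing_cols <- setdiff(.AGE_BAND_COLS, names(ab))
  if (length(missing_cols))
    .fail("age_bands", paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (any(ab$age_lo < 17)) .fail("age_bands.age_lo", "minimum modelled age is 17")
  if (is.unsorted(ab$age_lo, strictly = TRUE)) .fail("age_bands.age_lo", "bands must be ascending")
  if (abs(sum(ab$fraction) - 1) > 1e-9) .fail("age_bands.fraction", "must sum to 1")
  if (any(ab$fraction < 0)) .fail("age_bands.fraction", "must be non-negative")
  rate_cols <- c("mortality", "incidence_diabetes", "incidence_hypertension",
                 "complication_diabetes_cvd", "complication_hypertension_stroke")
  for (cl in rate_cols)
    if (any(ab[[cl]] < 0)) .fail(paste0("age_bands.", cl), "rates must be >= 0")
  prev <- as.matrix(ab[, c("prev_healthy", "prev_diabetes", "prev_hypertension")])
  if (any(prev < 0 | prev > 1)) .fail("age_bands.prev_*", "prevalences must lie in [0,1]")
  if (any(abs(rowSums(prev) - 1) > 1e-9))
    .fail("age_bands.prev_*", "disease prevalence must sum to 1 per band")

  pp <- params$pa_prevalence
  if (!is.matrix(pp) || !all(dim(pp) == c(3, 3)))
    .fail("pa_prevalence", "must be a 3x3 matrix (group x PA level)")
  if (any(pp < 0 | pp > 1)) .fail("pa_prevalence", "entries must lie in [0,1]")
  if (any(abs(rowSums(pp) - 1) > 1e-9)) .fail("pa_prevalence", "rows must sum to 1")

  ri <- params$rr_incidence
  if (!is.matrix(ri) || !all(dim(ri) == c(4, 3))) .fail("rr_incidence", "must be 4x3")
  if (any(ri < 0)) .fail("rr_incidence", "relative risks must be >= 0")
  if (any(ri[, 1] != 1)) .fail("rr_incidence", "inactive (reference) column must be exactly 1")

  rm_ <- params$rr_mortality
  if (!is.matrix(rm_) || !all(dim(rm_) == c(3, 3))) .fail("rr_mortality", "must be 3x3")
  if (any(rm_ < 0)) .fail("rr_mortality", "relative risks must be >= 0")
  if (any(rm_[, 1] != 1)) .fail("rr_mortality", "inactive (reference) column must be exactly 1")

  cm <- params$complication_mortality
  if (length(cm) != 2 || !all(COMPLICATIONS %in% names(cm)))
    .fail("complication_mortality", "needs named entries diabetes_cvd, hypertension_stroke")
  if (any(cm < 0)) .fail("complication_mortality", "multipliers must be >= 0")

  ub <- params$utilities$base
  need_u <- c("healthy", "diabetes", "hypertension", COMPLICATIONS)
  if (!all(need_u %in% names(ub))) .fail("utilities.base", "missing named utilities")
  if (any(ub < 0 | ub > 1)) .fail("utilities.base", "utilities must lie in [0,1]")
  if (ub["diabetes_cvd"] > ub["diabetes"] + 1e-12)
    .fail("utilities.base.diabetes_cvd", "complication utility must not exceed parent disease utility")
  if (ub["hypertension_stroke"] > ub["hypertension"] + 1e-12)
    .fail("utilities.base.hypertension_stroke", "complication utility must not exceed parent disease utility")
  pd <- params$utilities$pa_delta
  if (length(pd) != 3 || any(pd < 0)) .fail("utilities.pa_delta", "must be 3 non-negative values")

  cst <- params$costs
  if (!all(c("diabetes", "hypertension", COMPLICATIONS) %in% names(cst$inpatient)))
    .fail("costs.inpatient", "missing named entries")
  if (any(cst$inpatient < 0)) .fail("costs.inpatient", "costs must be >= 0")
  if (!all(c("diabetes", "hypertension") %in% names(cst$outpatient)))
    .fail("costs.outpatient", "missing named entries")
  if (any(cst$outpatient < 0)) .fail("costs.outpatient", "costs must be >= 0")
  ip <- cst$inpatient_proportion
  if (!all(c("diabetes", "hypertension") %in% names(ip)))
    .fail("costs.inpatient_proportion", "missing named entries")
  if (any(ip < 0 | ip > 1)) .fail("costs.inpatient_proportion", "must lie in [0,1]")
  if (length(cst$pa_multiplier) != 3 || any(cst$pa_multiplier < 0))
    .fail("costs.pa_multiplier", "must be 3 non-negative values")

  dir_ <- params$direct_indirect_ratio
  if (!all(c("diabetes", "hypertension") %in% names(dir_)))
    .fail("direct_indirect_ratio", "missing named entries")
  if (any(dir_ <= 0)) .fail("direct_indirect_ratio", "ratios must be > 0")

  for (nm in c("intervention_pa_shift", "control_pa_shift")) {
    S <- params[[nm]]
    if (!is.matrix(S) || !all(dim(S) == c(3, 3))) .fail(nm, "must be a 3x3 matrix")
    if (any(S < 0 | S > 1)) .fail(nm, "entries must lie in [0,1]")
    if (any(abs(rowSums(S) - 1) > 1e-9)) .fail(nm, "rows must sum to 1")
  }

  if (params$program_cost_annual < 0) .fail("program_cost_annual", "must be >= 0")
  if (params$compliance < 0 || params$compliance > 1) .fail("compliance", "must lie in [0,1]")
  if (params$n_registered <= 0) .fail("n_registered", "must be > 0")
  if (params$incidence_scale < 0) .fail("incidence_scale", "must be >= 0")
  if (params$discount_rate < 0) .fail("discount_rate", "must be >= 0")
  if (params$horizon_years < 1) .fail("horizon_years", "must be >= 1")
  if (params$cycle_length <= 0) .fail("cycle_length", "must be > 0")
  if (is.unsorted(params$wtp_grid)) .fail("wtp_grid", "must be sorted ascending")

  dists <- params$distributions
  if (nrow(dists)) {
    for (i in seq_len(nrow(dists))) {
      check_dist_parameters(dists$family[i], dists$p1[i], dists$p2[i], dists$name[i])
      get_parameter(params, dists$name[i]) # errors if the name resolves nowhere
    }
    if (anyDuplicated(dists$name)) .fail("distributions", "duplicate parameter names")
  }
  invisible(params)
}

# ---- age-band helpers --------------------------------------------------------

n_bands <- function(params) nrow(params$age_bands)

# representative age of each band: floor of the midpoint (open-ended last band
# is given a representative age 2 years above its lower bound + 0; see synth)
band_rep_age <- function(params) {
  ab <- params$age_bands
  hi <- pmin(ab$age_hi, ab$age_lo + 9) # cap open-ended bands
  floor((ab$age_lo + hi) / 2)
}

# band index containing a given (integer) age; ages past the last band stay in it
age_to_band <- function(params, age) {
  idx <- findInterval(age, params$age_bands$age_lo)
  pmin(pmax(idx, 1L), n_bands(params))
}

# ---- named scalar parameter access ------------------------------------------

.PA_NONREF <- c("low", "mod_high")

#' Names of the uncertain scalar parameters
#'
#' @param params A `parameter_set`.
#' @return Character vector of dot-path names present in `params$distributions`.
#' @export
uncertain_parameter_names <- function(params) params$distributions$name

#' Read a scalar parameter by name
#'
#' Dot-path addressing of the scalar parameters the sensitivity analyses vary,
#' e.g. `"rr_incidence.diabetes.low"`, `"utility.diabetes_cvd"`,
#' `"cost_inpatient.diabetes"`, `"inpatient_proportion.hypertension"`,
#' `"program_cost_annual"`, `"compliance"`, `"incidence_scale"`,
#' `"horizon_years"`.
#'
#' @param params A `parameter_set`.
#' @param name Parameter name.
#' @return Numeric scalar.
#' @export
get_parameter <- function(params, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  head <- parts[1]
  out <- switch(head,
    rr_incidence = params$rr_incidence[parts[2], parts[3]],
    rr_mortality = if (parts[2] %in% COMPLICATIONS) params$complication_mortality[parts[2]]
                   else params$rr_mortality[parts[2], parts[3]],
    utility = params$utilities$base[parts[2]],
    cost_inpatient = params$costs$inpatient[parts[2]],
    cost_outpatient = params$costs$outpatient[parts[2]],
    inpatient_proportion = params$costs$inpatient_proportion[parts[2]],
    direct_indirect_ratio = params$direct_indirect_ratio[parts[2]],
    program_cost_annual = params$program_cost_annual,
    compliance = params$compliance,
    incidence_scale = params$incidence_scale,
    discount_rate = params$discount_rate,
    horizon_years = params$horizon_years,
    NULL
  )
  if (is.null(out) || length(out) != 1 || is.na(out))
    stop("unknown parameter name: '", name, "'", call. = FALSE)
  unname(as.numeric(out))
}

#' Set a scalar parameter by name
#'
#' @inheritParams get_parameter
#' @param value New value.
#' @param validate Re-run full validation afterwards (default `FALSE`; the
#'   sensitivity analyses validate once after all assignments).
#' @return The modified `parameter_set`.
#' @export
set_parameter <- function(params, name, value, validate = FALSE) {
  get_parameter(params, name) # existence check
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  head <- parts[1]
  switch(head,
    rr_incidence = params$rr_incidence[parts[2], parts[3]] <- value,
    rr_mortality = if (parts[2] %in% COMPLICATIONS)
                     params$complication_mortality[parts[2]] <- value
                   else params$rr_mortality[parts[2], parts[3]] <- value,
    utility = params$utilities$base[parts[2]] <- value,
    cost_inpatient = params$costs$inpatient[parts[2]] <- value,
    cost_outpatient = params$costs$outpatient[parts[2]] <- value,
    inpatient_proportion = params$costs$inpatient_proportion[parts[2]] <- value,
    direct_indirect_ratio = params$direct_indirect_ratio[parts[2]] <- value,
    program_cost_annual = params$program_cost_annual <- value,
    compliance = params$compliance <- value,
    incidence_scale = params$incidence_scale <- value,
    discount_rate = params$discount_rate <- value,
    horizon_years = params$horizon_years <- as.integer(round(value))
  )
  if (validate) validate_parameter_set(params)
  params
}

# domain of a named parameter: c(lo, hi) used for DSA clamping and PSA
# truncation. Probabilities/utilities live in [0,1]; everything else in [0,Inf).
parameter_domain <- function(name) {
  head <- strsplit(name, ".", fixed = TRUE)[[1]][1]
  if (head %in% c("utility", "inpatient_proportion") || name == "compliance")
    c(0, 1) else c(0, Inf)
}

# After joint PSA sampling, restore the structural constraints the state model
# assumes: complication utility cannot exceed its parent disease utility, and
# the healthy utility caps both diseases. Truncation at the boundary, recorded
# here rather than silently inside the sampler.
enforce_parameter_consistency <- function(params) {
  ub <- params$utilities$base
  ub["diabetes"] <- min(ub["diabetes"], ub["healthy"])
  ub["hypertension"] <- min(ub["hypertension"], ub["healthy"])
  ub["diabetes_cvd"] <- min(ub["diabetes_cvd"], ub["diabetes"])
  ub["hypertension_stroke"] <- min(ub["hypertension_stroke"], ub["hypertension"])
  params$utilities$base <- ub
  params
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat("  age bands:", n_bands(x), " horizon:", x$horizon_years, "y",
      " discount:", x$discount_rate, "(", x$discount_timing, ")\n")
  cat("  cohort: ", format(x$n_registered, big.mark = ","), "registered x",
      x$compliance, "compliance\n")
  cat("  program cost/yr: SGD", format(x$program_cost_annual, big.mark = ","), "\n")
  cat("  uncertain parameters:", nrow(x$distributions), "\n")
  invisible(x)
}
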
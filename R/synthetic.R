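# Synthetic parameterisation. The generator emulates the structure of the
# study's supplementary parameter table: ~33 uncertain parameters with stated
# distribution families, age profiles with realistic shape, and headline
# economics anchored to the main-text figures (SGD 36M/yr program cost, 38.5%
# compliance, 3% discount, 10-year horizon, 1.7M registrants). All other
# magnitudes are documented plausible stand-ins, not the study's values.

.full_band_fractions <- c(0.045, 0.080, 0.095, 0.090, 0.090, 0.090, 0.090,
                          0.085, 0.080, 0.075, 0.060, 0.045, 0.032, 0.023, 0.020)

.full_age_bands <- function() {
  lo <- c(17, seq(20, 85, by = 5))
  hi <- c(19, seq(24, 84, by = 5), 120)
  data.frame(band = paste0(lo, "-", ifelse(hi == 120, "plus", hi)),
             age_lo = lo, age_hi = hi, stringsAsFactors = FALSE)
}

.toy_age_bands <- function() {
  data.frame(band = c("17-39", "40-64", "65-plus"),
             age_lo = c(17, 40, 65), age_hi = c(39, 64, 120),
             stringsAsFactors = FALSE)
}

# smooth age profiles used for the synthetic epidemiology
.age_profiles <- function(age) {
  list(
    mortality = 0.0002 * exp(0.085 * (age - 18)),
    incidence_diabetes = 0.0028 * exp(0.040 * (age - 18)),
    incidence_hypertension = 0.0055 * exp(0.040 * (age - 18)),
    complication_diabetes_cvd = 0.028 * exp(0.020 * (age - 18)),
    complication_hypertension_stroke = 0.018 * exp(0.025 * (age - 18)),
    prev_diabetes = 0.30 / (1 + exp(-(age - 62) / 12)),
    prev_hypertension = 0.60 / (1 + exp(-(age - 60) / 10))
  )
}

#' Generate a complete synthetic parameter set
#'
#' Deterministic given `seed`: small multiplicative jitters differentiate
#' seeds while every qualitative constraint the model assumes holds by
#' construction (prevalence/incidence/mortality increasing with age, relative
#' risks at or below 1 for higher PA levels with inactive as reference,
#' utilities ordered healthy >= disease >= complication, complication
#' inpatient costs highest). At `"full"` scale the distributions table carries
#' exactly 33 uncertain parameters; `"toy"` scale uses 3 coarse age bands for
#' fast exact tests.
#'
#' @param seed Integer seed.
#' @param scale `"full"` (15 five-year bands from 17-19 to 85+) or `"toy"`.
#' @return A validated `parameter_set`.
#' @export
generate_parameter_set <- function(seed = 1L, scale = c("full", "toy")) {
  scale <- match.arg(scale)
  set.seed(as.integer(seed) %% 2147483647L)
  jit <- function(n = 1, amt = 0.10) runif(n, 1 - amt, 1 + amt)

  bands <- if (scale == "full") .full_age_bands() else .toy_age_bands()
  nb <- nrow(bands)
  rep_age <- floor((bands$age_lo + pmin(bands$age_hi, bands$age_lo + 9)) / 2)
  prof <- .age_profiles(rep_age)

  frac <- if (scale == "full") .full_band_fractions else c(0.45, 0.38, 0.17)
  frac <- frac * jit(nb, 0.05)
  frac <- frac / sum(frac)

  prev_d <- pmin(0.45, prof$prev_diabetes * jit(nb, 0.08))
  prev_h <- pmin(0.60, prof$prev_hypertension * jit(nb, 0.08))
  age_bands <- data.frame(
    bands,
    fraction = frac,
    mortality = prof$mortality * jit(nb, 0.05),
    incidence_diabetes = prof$incidence_diabetes * jit(nb, 0.08),
    incidence_hypertension = prof$incidence_hypertension * jit(nb, 0.08),
    complication_diabetes_cvd = prof$complication_diabetes_cvd * jit(nb, 0.08),
    complication_hypertension_stroke = prof$complication_hypertension_stroke * jit(nb, 0.08),
    prev_diabetes = prev_d,
    prev_hypertension = prev_h,
    stringsAsFactors = FALSE
  )
  age_bands$prev_healthy <- 1 - age_bands$prev_diabetes - age_bands$prev_hypertension
  age_bands <- age_bands[, .AGE_BAND_COLS]

  norm_rows <- function(m) m / rowSums(m)
  pa_prevalence <- norm_rows(rbind(
    healthy = c(0.22, 0.36, 0.42) * jit(3, 0.05),
    diabetes = c(0.35, 0.37, 0.28) * jit(3, 0.05),
    hypertension = c(0.32, 0.38, 0.30) * jit(3, 0.05)
  ))
  colnames(pa_prevalence) <- PA_LEVELS

  rr_row <- function(low, high, amt = 0.04) c(1, low * jit(1, amt), high * jit(1, amt))
  rr_incidence <- rbind(
    diabetes = rr_row(0.87, 0.72),
    hypertension = rr_row(0.89, 0.76),
    diabetes_cvd = rr_row(0.82, 0.66),
    hypertension_stroke = rr_row(0.83, 0.68)
  )
  colnames(rr_incidence) <- PA_LEVELS
  rr_incidence[] <- pmin(rr_incidence, 1)
  rr_incidence[, 1] <- 1

  rr_mortality <- rbind(
    healthy = rr_row(0.82, 0.68),
    diabetes = rr_row(0.85, 0.72),
    hypertension = rr_row(0.84, 0.71)
  )
  colnames(rr_mortality) <- PA_LEVELS
  rr_mortality[] <- pmin(rr_mortality, 1)
  rr_mortality[, 1] <- 1
  complication_mortality <- c(diabetes_cvd = 2.6 * jit(1, 0.05),
                              hypertension_stroke = 3.1 * jit(1, 0.05))

  u_healthy <- min(0.97, 0.94 * jit(1, 0.02))
  u_diab <- min(u_healthy - 0.02, 0.84 * jit(1, 0.03))
  u_hyp <- min(u_healthy - 0.02, 0.87 * jit(1, 0.03))
  utilities <- list(
    base = c(healthy = u_healthy, diabetes = u_diab, hypertension = u_hyp,
             diabetes_cvd = min(u_diab - 0.05, 0.71 * jit(1, 0.04)),
             hypertension_stroke = min(u_hyp - 0.05, 0.64 * jit(1, 0.04))),
    pa_delta = c(0, 0.015, 0.03)
  )

  cin_d <- 8000 * jit(1, 0.06); cin_h <- 6000 * jit(1, 0.06)
  costs <- list(
    inpatient = c(diabetes = cin_d, hypertension = cin_h,
                  diabetes_cvd = max(cin_d * 1.8, 22000 * jit(1, 0.06)),
                  hypertension_stroke = max(cin_h * 1.8, 19000 * jit(1, 0.06))),
    outpatient = c(diabetes = 2200 * jit(1, 0.06), hypertension = 1100 * jit(1, 0.06)),
    inpatient_proportion = c(diabetes = 0.12 * jit(1, 0.06),
                             hypertension = 0.08 * jit(1, 0.06)),
    pa_multiplier = c(1, 1, 1)
  )

  direct_indirect_ratio <- c(diabetes = 0.45 * jit(1, 0.08),
                             hypertension = 0.50 * jit(1, 0.08))

  intervention_pa_shift <- norm_rows(rbind(
    c(0.55, 0.30, 0.15),
    c(0.03, 0.67, 0.30),
    c(0.01, 0.04, 0.95)
  ))
  control_pa_shift <- diag(3)

  params <- parameter_set(
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
    program_cost_annual = 36e6,
    compliance = 0.385,
    n_registered = 1.7e6,
    incidence_scale = 1,
    discount_rate = 0.03,
    horizon_years = 10L,
    cycle_length = 1,
    wtp_grid = c(0, 5000, 10000),
    discount_timing = "end"
  )
  params$distributions <- default_distributions(params)
  rownames(params$distributions) <- NULL
  validate_parameter_set(params)
  params
}

#' Default uncertainty distributions for a parameter set
#'
#' Builds the 33-row distributions table: lognormal for relative risks and the
#' incidence scale (95% CI roughly +/-15-20%), beta for utilities, inpatient
#' proportions and compliance, gamma for costs (IQR range rule) and the
#' program cost, uniform for the horizon. Range rules follow the study design:
#' 95% CIs except IQR for treatment costs and +/-30% for inpatient
#' proportions, program cost, compliance and horizon.
#'
#' @param params A `parameter_set` supplying the base values.
#' @return Data frame of [dist_spec()] rows.
#' @export
default_distributions <- function(params) {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- dist_spec(...)

  for (dis in rownames(params$rr_incidence))
    for (lv in c("low", "mod_high")) {
      b <- params$rr_incidence[dis, lv]
      add(paste("rr_incidence", dis, lv, sep = "."), "lognormal", log(b), 0.08, "ci95")
    }
  for (grp in rownames(params$rr_mortality))
    for (lv in c("low", "mod_high")) {
      b <- params$rr_mortality[grp, lv]
      add(paste("rr_mortality", grp, lv, sep = "."), "lognormal", log(b), 0.08, "ci95")
    }
  for (cp in COMPLICATIONS)
    add(paste("rr_mortality", cp, sep = "."), "lognormal",
        log(params$complication_mortality[cp]), 0.10, "ci95")
  for (nm in names(params$utilities$base)) {
    sh <- beta_from_mean_sd(params$utilities$base[nm], 0.02)
    add(paste("utility", nm, sep = "."), "beta", sh[1], sh[2], "ci95")
  }
  for (nm in names(params$costs$inpatient)) {
    sh <- gamma_from_mean_sd(params$costs$inpatient[nm], 0.25 * params$costs$inpatient[nm])
    add(paste("cost_inpatient", nm, sep = "."), "gamma", sh[1], sh[2], "iqr")
  }
  for (nm in names(params$costs$outpatient)) {
    sh <- gamma_from_mean_sd(params$costs$outpatient[nm], 0.25 * params$costs$outpatient[nm])
    add(paste("cost_outpatient", nm, sep = "."), "gamma", sh[1], sh[2], "iqr")
  }
  for (nm in names(params$costs$inpatient_proportion)) {
    sh <- beta_from_mean_sd(params$costs$inpatient_proportion[nm],
                            0.15 * params$costs$inpatient_proportion[nm])
    add(paste("inpatient_proportion", nm, sep = "."), "beta", sh[1], sh[2], "pm30")
  }
  add("incidence_scale", "lognormal", log(params$incidence_scale), 0.10, "ci95")
  shp <- gamma_from_mean_sd(params$program_cost_annual,
                            (0.3 / 1.96) * params$program_cost_annual)
  add("program_cost_annual", "gamma", shp[1], shp[2], "pm30")
  shc <- beta_from_mean_sd(params$compliance, (0.3 / 1.96) * params$compliance)
  add("compliance", "beta", shc[1], shc[2], "pm30")
  add("horizon_years", "uniform", 0.7 * params$horizon_years,
      1.3 * params$horizon_years, "pm30")

  do.call(rbind, rows)
}

#' Generate an age-banded population
#'
#' Multinomial allocation of `n` persons across the age bands of an age
#' specification (minimum age 17).
#'
#' @param seed Integer seed.
#' @param n Population size.
#' @param age_spec Data frame with columns `band` and `fraction` (e.g.
#'   `params$age_bands`).
#' @return Data frame with `band`, `fraction`, `count`; counts sum to `n`.
#' @export
generate_population <- function(seed, n, age_spec) {
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  if (abs(sum(age_spec$fraction) - 1) > 1e-9)
    stop("age_spec$fraction must sum to 1", call. = FALSE)
  set.seed(as.integer(seed) %% 2147483647L)
  counts <- as.integer(stats::rmultinom(1, n, age_spec$fraction))
  data.frame(band = age_spec$band, fraction = age_spec$fraction,
             count = counts, stringsAsFactors = FALSE)
}
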
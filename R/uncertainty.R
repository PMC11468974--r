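# Uncertainty analyses: probabilistic sensitivity analysis (PSA), one-way
# deterministic sensitivity (tornado), deterministic threshold (break-even)
# search and the PA cost-differentiation scenario.

# one RNG stream per parameter, derived from the master seed, so adding or
# removing a parameter never perturbs the draws of the others
.param_stream_seed <- function(seed, j) {
  (as.numeric(seed) * 1009 + j * 7919) %% 2147483647
}

#' Probabilistic sensitivity analysis
#'
#' Draws all uncertain parameters jointly and independently from their
#' prespecified distributions (`horizon_years` is never sampled), runs the full
#' model — both situations — per draw, and summarises each incremental quantity
#' by its sample mean and 2.5/97.5 percentiles, plus the CEAC over the WTP
#' grid. The cohort size of each draw is `n_registered x` the drawn compliance.
#'
#' @param params A `parameter_set` whose `distributions` table covers every
#'   uncertain parameter.
#' @param n_samples Number of Monte Carlo samples (the study design uses 1000).
#' @param seed Master seed; each parameter gets an independent sub-stream.
#' @param perspective `"health_system"` or `"societal"`.
#' @return A `psa_result`: `samples` (data frame, one row per draw), `means`,
#'   `ci_lo`, `ci_hi` (2.5/97.5 percentiles, linear interpolation between order
#'   statistics), `ceac`, `seed`, `n_samples`.
#' @export
run_psa <- function(params, n_samples = 1000L, seed = 1L,
                    perspective = c("health_system", "societal")) {
  perspective <- match.arg(perspective)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  dists <- params$distributions
  if (!nrow(dists)) stop("no uncertain parameters: distributions table is empty", call. = FALSE)
  for (i in seq_len(nrow(dists)))
    check_dist_parameters(dists$family[i], dists$p1[i], dists$p2[i], dists$name[i])
  dists <- dists[dists$name != "horizon_years", , drop = FALSE]

  draws <- matrix(NA_real_, n_samples, nrow(dists),
                  dimnames = list(NULL, dists$name))
  for (j in seq_len(nrow(dists))) {
    set.seed(.param_stream_seed(seed, j))
    x <- sample_distribution(dists$family[j], dists$p1[j], dists$p2[j], n_samples)
    dom <- parameter_domain(dists$name[j])
    draws[, j] <- pmin(pmax(x, dom[1]), dom[2])
  }

  cols <- c("cases_averted_diabetes", "cases_averted_hypertension",
            "deaths_averted", "qalys_gained", "cost_reduction",
            "program_cost", "icer", "cohort_size")
  samples <- as.data.frame(matrix(NA_real_, n_samples, length(cols),
                                  dimnames = list(NULL, cols)))
  for (i in seq_len(n_samples)) {
    p_i <- params
    for (j in seq_len(ncol(draws)))
      p_i <- set_parameter(p_i, colnames(draws)[j], draws[i, j])
    p_i <- enforce_parameter_consistency(p_i)
    n_i <- estimate_cohort_size(p_i$n_registered, p_i$compliance)
    res <- run_incremental(p_i, n = n_i, perspective = perspective)
    samples[i, ] <- c(res$cases_averted_diabetes, res$cases_averted_hypertension,
                      res$deaths_averted, res$qalys_gained, res$cost_reduction,
                      res$program_cost, as.numeric(res$icer), n_i)
  }

  q <- function(v, p) as.numeric(quantile(v, p, na.rm = TRUE, type = 7))
  means <- vapply(samples, mean, numeric(1))
  ci_lo <- vapply(samples, q, numeric(1), p = 0.025)
  ci_hi <- vapply(samples, q, numeric(1), p = 0.975)
  delta_cost <- samples$program_cost - samples$cost_reduction
  curve <- ceac(delta_cost, samples$qalys_gained, params$wtp_grid)

  structure(list(samples = samples, means = means, ci_lo = ci_lo, ci_hi = ci_hi,
                 ceac = curve, seed = seed, n_samples = n_samples,
                 perspective = perspective),
            class = "psa_result")
}

#' Deterministic ICER for a parameter set
#'
#' Convenience wrapper: runs both situations at the derived cohort size and
#' returns the bare ICER (SGD/QALY, `NA` when undefined).
#'
#' @param params A `parameter_set`.
#' @param perspective `"health_system"` or `"societal"`.
#' @return Numeric scalar.
#' @export
deterministic_icer <- function(params, perspective = "health_system") {
  as.numeric(run_incremental(params, perspective = perspective)$icer)
}

# low/high DSA bounds for one distribution-spec row, clamped to the parameter's
# domain (with a warning) when a range rule overshoots it
dsa_bounds <- function(spec, base_value) {
  b <- switch(spec$range_rule,
    ci95 = quantile_distribution(spec$family, spec$p1, spec$p2, c(0.025, 0.975)),
    iqr = quantile_distribution(spec$family, spec$p1, spec$p2, c(0.25, 0.75)),
    pm30 = c(0.7, 1.3) * base_value
  )
  dom <- parameter_domain(spec$name)
  clamped <- pmin(pmax(b, dom[1]), dom[2])
  if (any(clamped != b))
    warning("DSA bounds for '", spec$name, "' clamped to [", dom[1], ", ", dom[2], "]",
            call. = FALSE)
  clamped
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Each parameter in turn is set to the low and high bound implied by its
#' `range_rule` (95% CI, IQR or +/-30%) with all others at base values, the
#' deterministic model is re-run, and the two ICERs are recorded. Entries are
#' returned sorted by descending bar width. `horizon_years` bounds are rounded
#' to whole cycles.
#'
#' @param params A `parameter_set`.
#' @param parameters Names to vary; default all names in the distributions
#'   table (including `horizon_years`).
#' @param perspective `"health_system"` or `"societal"`.
#' @return Data frame with `parameter`, `low`, `high`, `icer_low`, `icer_high`,
#'   `width`, sorted by descending `width`.
#' @export
one_way_dsa <- function(params, parameters = NULL, perspective = "health_system") {
  dists <- params$distributions
  if (is.null(parameters)) parameters <- dists$name
  missing_p <- setdiff(parameters, dists$name)
  if (length(missing_p))
    stop("no distribution spec for: ", paste(missing_p, collapse = ", "), call. = FALSE)
  base_icer <- deterministic_icer(params, perspective)

  rows <- lapply(parameters, function(nm) {
    spec <- dists[dists$name == nm, ]
    base <- get_parameter(params, nm)
    b <- dsa_bounds(spec, base)
    if (nm == "horizon_years") b <- round(b)
    eval_at <- function(v) {
      p <- enforce_parameter_consistency(set_parameter(params, nm, v))
      deterministic_icer(p, perspective)
    }
    lo_icer <- eval_at(b[1])
    hi_icer <- eval_at(b[2])
    data.frame(parameter = nm, low = b[1], high = b[2],
               icer_low = lo_icer, icer_high = hi_icer,
               width = abs(hi_icer - lo_icer), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  out
}

#' Threshold (break-even) analysis by bisection
#'
#' Finds the value of one parameter at which the deterministic ICER crosses
#' zero (the cost-saving boundary), all other parameters at base values.
#'
#' @param params A `parameter_set`.
#' @param parameter Name of the parameter to solve over.
#' @param bracket Length-2 numeric search interval.
#' @param tol Absolute bracket-width tolerance; default `1e-6` of the initial
#'   bracket width.
#' @param perspective `"health_system"` or `"societal"`.
#' @return A `threshold_result`: `parameter`, `threshold` (or `NA`),
#'   `direction` (`"at_least"` / `"at_most"`), `bracket`, `tol`,
#'   `icer_at_threshold`, `found`.
#' @export
threshold_search <- function(params, parameter, bracket, tol = NULL,
                             perspective = "health_system") {
  if (length(bracket) != 2 || bracket[1] >= bracket[2])
    stop("bracket must be c(lo, hi) with lo < hi", call. = FALSE)
  if (is.null(tol)) tol <- 1e-6 * diff(bracket)
  f <- function(v) {
    p <- enforce_parameter_consistency(set_parameter(params, parameter, v))
    deterministic_icer(p, perspective)
  }
  f_lo <- f(bracket[1]); f_hi <- f(bracket[2])
  if (is.na(f_lo) || is.na(f_hi) || f_lo * f_hi > 0) {
    return(structure(list(parameter = parameter, threshold = NA_real_,
                          direction = NA_character_, bracket = bracket, tol = tol,
                          icer_at_threshold = NA_real_, found = FALSE),
                     class = "threshold_result"))
  }
  lo <- bracket[1]; hi <- bracket[2]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (f_mid == 0) { lo <- hi <- mid; break }
    if (f_lo * f_mid < 0) { hi <- mid; f_hi <- f_mid } else { lo <- mid; f_lo <- f_mid }
  }
  root <- (lo + hi) / 2
  # cost-saving (ICER < 0) on the high side means the parameter must be at
  # least the threshold; on the low side, at most
  direction <- if (f(bracket[2]) < 0) "at_least" else "at_most"
  structure(list(parameter = parameter, threshold = root, direction = direction,
                 bracket = bracket, tol = tol, icer_at_threshold = f(root),
                 found = TRUE),
            class = "threshold_result")
}

#' Scenario: differentiate costs by physical-activity level
#'
#' Returns a copy of the parameter set in which, within each uncomplicated
#' disease state, annual costs of the inactive level are inflated by `delta`
#' and those of the moderate-to-high level deflated by `delta`; the low level
#' and the complication states are unchanged. `delta = 0` is the base case
#' (equal costs across PA levels).
#'
#' @param params A `parameter_set`.
#' @param delta Fraction in `[0, 1)`; the study's scenario uses 0.05.
#' @return Modified `parameter_set`.
#' @export
apply_cost_differentiation <- function(params, delta = 0.05) {
  if (delta < 0 || delta >= 1) stop("delta must lie in [0, 1)", call. = FALSE)
  params$costs$pa_multiplier <- c(1 + delta, 1, 1 - delta)
  params
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$n_samples, "samples, seed", x$seed,
      ", perspective:", x$perspective, "\n")
  show <- c("qalys_gained", "cost_reduction", "program_cost")
  for (nm in show)
    cat(sprintf("  %s: mean %.4g (%.4g to %.4g)\n", nm, x$means[nm],
                x$ci_lo[nm], x$ci_hi[nm]))
  cat("  CEAC:", paste(sprintf("P(CE|%g)=%.3f", x$ceac$wtp, x$ceac$probability),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.threshold_result <- function(x, ...) {
  if (!x$found) {
    cat("<threshold_result>", x$parameter, ": no ICER sign change in bracket [",
        x$bracket[1], ",", x$bracket[2], "]\n")
  } else {
    cat("<threshold_result>", x$parameter, if (x$direction == "at_least") ">=" else "<=",
        signif(x$threshold, 6), "(|ICER| at root:", signif(abs(x$icer_at_threshold), 3), ")\n")
  }
  invisible(x)
}
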
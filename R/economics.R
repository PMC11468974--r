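# Incremental cost-effectiveness: ICER, cost-saving classification, societal
# costs, cost-effectiveness probabilities and the acceptability curve.

#' Incremental cost-effectiveness ratio
#'
#' `(program_cost - cost_reduction) / qalys_gained`. A zero QALY gain yields an
#' undefined ICER, signalled as `NA` with attribute `undefined = TRUE` so
#' consumers can fall back to net-monetary-benefit logic.
#'
#' @param program_cost Total (discounted) program cost, SGD.
#' @param cost_reduction Reduction in health-care (or societal) costs, SGD.
#' @param qalys_gained Incremental QALYs.
#' @return SGD per QALY gained (negative when cost-saving), or `NA` if
#'   `qalys_gained == 0`.
#' @export
icer <- function(program_cost, cost_reduction, qalys_gained) {
  if (qalys_gained == 0)
    return(structure(NA_real_, undefined = TRUE))
  (program_cost - cost_reduction) / qalys_gained
}

#' Classify the cost-effectiveness quadrant
#'
#' Cost-saving means positive QALYs gained and a health-care cost reduction
#' exceeding the program cost (equivalently, positive QALYs with a negative
#' ICER).
#'
#' @inheritParams icer
#' @return One of `"cost-saving"`, `"cost-effective computation required"`
#'   (positive QALYs, positive net cost), `"dominated"` (QALYs lost at net
#'   cost), `"undefined"` (zero QALY change).
#' @export
classify_icer <- function(program_cost, cost_reduction, qalys_gained) {
  net_cost <- program_cost - cost_reduction
  if (qalys_gained > 0 && net_cost < 0) return("cost-saving")
  if (qalys_gained > 0) return("cost-effective computation required")
  if (qalys_gained == 0) return("undefined")
  if (net_cost >= 0) return("dominated")
  "less effective, less costly"
}

#' Societal cost from direct costs and direct-to-indirect ratios
#'
#' Societal cost adds the indirect cost (`direct / ratio`) to the direct cost,
#' summed over diseases.
#'
#' @param direct Named numeric vector of direct costs per disease.
#' @param direct_indirect_ratio Named numeric vector of direct:indirect ratios
#'   for the same diseases (a ratio of 0.5 means indirect costs are twice the
#'   direct costs).
#' @return Total societal cost.
#' @export
societal_cost <- function(direct, direct_indirect_ratio) {
  if (any(direct_indirect_ratio <= 0))
    stop("direct_indirect_ratio must be > 0", call. = FALSE)
  ratio <- direct_indirect_ratio[names(direct)]
  sum(direct + direct / ratio)
}

#' Pair two outcome summaries into an incremental result
#'
#' @param intervention,control `outcome_summary` objects from [run_model()].
#' @param perspective `"health_system"` (direct costs only) or `"societal"`
#'   (direct + indirect).
#' @return An `incremental_result`: cases/deaths averted, QALYs gained, cost
#'   reduction, program cost, ICER and classification.
#' @export
incremental_result <- function(intervention, control,
                               perspective = c("health_system", "societal")) {
  perspective <- match.arg(perspective)
  reduction <- (control$direct_cost - intervention$direct_cost)
  if (perspective == "societal")
    reduction <- reduction + (control$indirect_cost - intervention$indirect_cost)
  qg <- intervention$qalys - control$qalys
  pc <- intervention$program_cost - control$program_cost
  structure(list(
    cases_averted_diabetes = control$cum_diabetes - intervention$cum_diabetes,
    cases_averted_hypertension = control$cum_hypertension - intervention$cum_hypertension,
    complications_averted = control$cum_complications - intervention$cum_complications,
    deaths_averted = control$cum_deaths - intervention$cum_deaths,
    qalys_gained = qg,
    cost_reduction = reduction,
    program_cost = pc,
    icer = icer(pc, reduction, qg),
    classification = classify_icer(pc, reduction, qg),
    perspective = perspective,
    n = intervention$n
  ), class = "incremental_result")
}

#' Run intervention and control and return the incremental result
#'
#' @param params A `parameter_set`.
#' @param n Cohort size; default `n_registered * compliance`.
#' @param perspective See [incremental_result()].
#' @return An `incremental_result` with both `outcome_summary` objects attached
#'   as attribute `"outcomes"`.
#' @export
run_incremental <- function(params, n = NULL,
                            perspective = c("health_system", "societal")) {
  perspective <- match.arg(perspective)
  intv <- run_model(params, "intervention", n = n)
  ctrl <- run_model(params, "control", n = n)
  res <- incremental_result(intv, ctrl, perspective)
  attr(res, "outcomes") <- list(intervention = intv, control = ctrl)
  res
}

#' Probability of cost-effectiveness at a willingness-to-pay threshold
#'
#' Net-monetary-benefit rule: the fraction of samples with
#' `wtp * dQALY - dCost > 0`, where `dCost = program_cost - cost_reduction`.
#' When every sample gains QALYs this equals the fraction of per-sample ICERs
#' below the threshold.
#'
#' @param delta_cost Per-sample incremental cost (program minus reduction).
#' @param delta_qaly Per-sample incremental QALYs.
#' @param wtp Willingness-to-pay, SGD/QALY.
#' @return Fraction in `[0, 1]`.
#' @export
ce_probability <- function(delta_cost, delta_qaly, wtp) {
  if (!length(delta_cost) || length(delta_cost) != length(delta_qaly))
    stop("delta_cost and delta_qaly must be nonempty and of equal length", call. = FALSE)
  mean(wtp * delta_qaly - delta_cost > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' @inheritParams ce_probability
#' @param wtp_grid Sorted ascending WTP values.
#' @return Data frame with `wtp`, `probability`, `complement`
#'   (`1 - probability`).
#' @export
ceac <- function(delta_cost, delta_qaly, wtp_grid) {
  if (is.unsorted(wtp_grid)) stop("wtp_grid must be sorted ascending", call. = FALSE)
  p <- vapply(wtp_grid, function(w) ce_probability(delta_cost, delta_qaly, w), numeric(1))
  data.frame(wtp = wtp_grid, probability = p, complement = 1 - p)
}

#' @export
print.incremental_result <- function(x, ...) {
  cat("<incremental_result> perspective:", x$perspective, "\n")
  cat(sprintf("  averted: diabetes %.0f, hypertension %.0f, deaths %.0f\n",
              x$cases_averted_diabetes, x$cases_averted_hypertension, x$deaths_averted))
  cat(sprintf("  QALYs gained %.1f | cost reduction SGD %.3g | program SGD %.3g\n",
              x$qalys_gained, x$cost_reduction, x$program_cost))
  if (is.na(x$icer)) cat("  ICER: undefined (", x$classification, ")\n")
  else cat(sprintf("  ICER: SGD %.0f per QALY (%s)\n", x$icer, x$classification))
  invisible(x)
}
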
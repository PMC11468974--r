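# Per-parameter uncertainty distributions. Families follow health-economics
# convention: beta for probabilities/utilities, gamma for costs, lognormal for
# relative risks; uniform and degenerate are available for special cases.

.DIST_FAMILIES <- c("beta", "gamma", "lognormal", "uniform", "degenerate")
.RANGE_RULES <- c("ci95", "iqr", "pm30")

#' Distribution specification
#'
#' Describes the uncertainty attached to one scalar model parameter: the
#' sampling family used in probabilistic sensitivity analysis and the
#' `range_rule` used to derive one-way sensitivity bounds (`ci95` = 2.5/97.5
#' distribution quantiles, `iqr` = 25/75 quantiles, `pm30` = base value
#' inflated/deflated by 30%).
#'
#' @param name Parameter name (dot path, e.g. `"rr_incidence.diabetes.low"`).
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"uniform"`,
#'   `"degenerate"`.
#' @param p1,p2 Family parameters: beta `shape1`/`shape2`; gamma `shape`/`rate`;
#'   lognormal `meanlog`/`sdlog`; uniform `min`/`max`; degenerate the value
#'   (`p2` ignored).
#' @param range_rule One of `"ci95"`, `"iqr"`, `"pm30"`.
#' @return A one-row data frame.
#' @export
dist_spec <- function(name, family, p1, p2 = NA_real_, range_rule = "ci95") {
  family <- match.arg(family, .DIST_FAMILIES)
  range_rule <- match.arg(range_rule, .RANGE_RULES)
  check_dist_parameters(family, p1, p2, name)
  data.frame(name = name, family = family, p1 = p1, p2 = p2,
             range_rule = range_rule, stringsAsFactors = FALSE)
}

check_dist_parameters <- function(family, p1, p2, name = "<unnamed>") {
  bad <- function(msg) stop("distribution for '", name, "': ", msg, call. = FALSE)
  if (!is.finite(p1)) bad("p1 must be finite")
  switch(family,
    beta = if (p1 <= 0 || !is.finite(p2) || p2 <= 0) bad("beta shapes must be > 0"),
    gamma = if (p1 <= 0 || !is.finite(p2) || p2 <= 0) bad("gamma shape/rate must be > 0"),
    lognormal = if (!is.finite(p2) || p2 < 0) bad("lognormal sdlog must be >= 0"),
    uniform = if (!is.finite(p2) || p2 < p1) bad("uniform needs min <= max"),
    degenerate = invisible(NULL)
  )
  invisible(TRUE)
}

#' Sample from a distribution specification
#'
#' @param family,p1,p2 See [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(family, p1, p2, n) {
  switch(family,
    beta = rbeta(n, p1, p2),
    gamma = rgamma(n, shape = p1, rate = p2),
    lognormal = rlnorm(n, meanlog = p1, sdlog = p2),
    uniform = runif(n, p1, p2),
    degenerate = rep(p1, n),
    stop("unknown distribution family: ", family, call. = FALSE)
  )
}

#' Quantiles of a distribution specification
#'
#' @param family,p1,p2 See [dist_spec()].
#' @param probs Probabilities.
#' @return Numeric vector of quantiles.
#' @export
quantile_distribution <- function(family, p1, p2, probs) {
  switch(family,
    beta = qbeta(probs, p1, p2),
    gamma = qgamma(probs, shape = p1, rate = p2),
    lognormal = qlnorm(probs, meanlog = p1, sdlog = p2),
    uniform = qunif(probs, p1, p2),
    degenerate = rep(p1, length(probs)),
    stop("unknown distribution family: ", family, call. = FALSE)
  )
}

# moment-matched helpers used by the synthetic generator
beta_from_mean_sd <- function(mean, sd) {
  v <- sd^2
  stopifnot(mean > 0, mean < 1, v < mean * (1 - mean))
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

gamma_from_mean_sd <- function(mean, sd) {
  shape <- (mean / sd)^2
  c(shape = shape, rate = shape / mean)
}
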
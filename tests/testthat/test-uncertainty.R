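test_that("degenerate distributions make every PSA sample equal the deterministic run", {
  p <- toy_params()
  p$distributions <- degenerate_distributions(p)
  ps <- run_psa(p, n_samples = 5, seed = 99)
  det <- run_incremental(p)
  for (i in 1:5) {
    expect_equal(ps$samples$qalys_gained[i], det$qalys_gained, tolerance = 1e-12)
    expect_equal(ps$samples$cost_reduction[i], det$cost_reduction, tolerance = 1e-12)
    expect_equal(ps$samples$program_cost[i], det$program_cost, tolerance = 1e-12)
  }
  expect_equal(unname(ps$ci_hi["qalys_gained"] - ps$ci_lo["qalys_gained"]), 0)
})

test_that("PSA is reproducible given the seed and summarises with interpolated percentiles", {
  p <- toy_params()
  a <- run_psa(p, n_samples = 40, seed = 7)
  b <- run_psa(p, n_samples = 40, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_identical(a$ceac, b$ceac)

  # percentile oracle: sorted-array linear interpolation between order statistics
  x <- sort(a$samples$qalys_gained)
  n <- length(x)
  manual_q <- function(prob) {
    h <- (n - 1) * prob + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
  }
  expect_equal(unname(a$ci_lo["qalys_gained"]), manual_q(0.025), tolerance = 1e-12)
  expect_equal(unname(a$ci_hi["qalys_gained"]), manual_q(0.975), tolerance = 1e-12)
  expect_equal(unname(a$means["qalys_gained"]), mean(a$samples$qalys_gained))
  expect_equal(a$n_samples, nrow(a$samples))
})

test_that("each parameter draws from its own seed-derived stream", {
  # make only the program cost uncertain: its draws must equal the stream
  # derived from (master seed, its table position), independent of the other
  # parameters' specifications
  p <- toy_params()
  d <- degenerate_distributions(p)
  j <- which(p$distributions$name == "program_cost_annual")
  d[j, ] <- p$distributions[j, ]
  p$distributions <- d
  ps <- run_psa(p, n_samples = 8, seed = 21)
  spec <- p$distributions[j, ]
  set.seed((21 * 1009 + j * 7919) %% 2147483647)
  draws <- rgamma(8, shape = spec$p1, rate = spec$p2)
  expect_equal(ps$samples$program_cost,
               draws * annuity(p$discount_rate, p$horizon_years), tolerance = 1e-9)
})

test_that("the time horizon is never sampled in the PSA", {
  p <- toy_params()
  expect_true("horizon_years" %in% p$distributions$name)
  ps <- run_psa(p, n_samples = 3, seed = 5)
  expect_false("horizon_years" %in% colnames(ps$samples))
  # horizon stays at base in every draw: program cost spans 10 cycles whenever
  # its draw is degenerate
  p$distributions <- degenerate_distributions(p)
  ps2 <- run_psa(p, n_samples = 2, seed = 5)
  expect_equal(ps2$samples$program_cost[1], p$program_cost_annual * annuity(0.03, 10),
               tolerance = 1e-9)
})

test_that("one-way DSA bounds follow the range rules and sort by bar width", {
  p <- toy_params()
  d <- one_way_dsa(p)
  expect_setequal(d$parameter, p$distributions$name)
  expect_true(all(diff(d$width) <= 1e-12))
  expect_true(all(d$width >= 0))
  # pm30 rule: program cost varied to 0.7x and 1.3x its base
  pc <- d[d$parameter == "program_cost_annual", ]
  expect_equal(pc$low, 0.7 * p$program_cost_annual)
  expect_equal(pc$high, 1.3 * p$program_cost_annual)
  # ci95 rule: lognormal RR bounds at the 2.5/97.5 quantiles
  nm <- "rr_incidence.diabetes.low"
  spec <- p$distributions[p$distributions$name == nm, ]
  rrow <- d[d$parameter == nm, ]
  expect_equal(rrow$low, qlnorm(0.025, spec$p1, spec$p2), tolerance = 1e-12)
  expect_equal(rrow$high, qlnorm(0.975, spec$p1, spec$p2), tolerance = 1e-12)
  # horizon bounds land on whole cycles
  hrow <- d[d$parameter == "horizon_years", ]
  expect_equal(hrow$low, 7)
  expect_equal(hrow$high, 13)
})

test_that("a parameter the model ignores produces a zero-width tornado bar", {
  p <- toy_params()
  # utilities of the hypertension-stroke state matter, but a zero-variance
  # (degenerate) parameter must reproduce the base ICER on both sides
  d0 <- p$distributions
  row <- d0$name == "utility.healthy"
  d0$family[row] <- "degenerate"
  d0$p1[row] <- get_parameter(p, "utility.healthy")
  d0$p2[row] <- NA
  p$distributions <- d0
  d <- one_way_dsa(p, parameters = "utility.healthy")
  expect_equal(d$width, 0)
  expect_equal(d$icer_low, attr(d, "base_icer"))
})

test_that("tornado bar width matches the affine closed form for the program cost", {
  p <- toy_params()
  res <- run_incremental(p)
  d <- one_way_dsa(p, parameters = "program_cost_annual")
  # ICER is affine in the annual program cost with slope annuity / QALYs gained
  slope <- annuity(p$discount_rate, p$horizon_years) / res$qalys_gained
  expect_equal(d$width, slope * 0.6 * p$program_cost_annual, tolerance = 1e-9)
})

test_that("tornado entries are invariant to parameter evaluation order", {
  p <- toy_params()
  nms <- c("program_cost_annual", "compliance", "utility.diabetes")
  a <- one_way_dsa(p, parameters = nms)
  b <- one_way_dsa(p, parameters = rev(nms))
  expect_equal(a[order(a$parameter), ], b[order(b$parameter), ], ignore_attr = TRUE)
})

test_that("bisection finds the analytic break-even program cost", {
  p <- toy_params()
  res <- run_incremental(p)
  # ICER crosses zero where program_cost_annual * annuity == cost reduction
  root_analytic <- res$cost_reduction / annuity(p$discount_rate, p$horizon_years)
  ts <- threshold_search(p, "program_cost_annual",
                         bracket = c(0, 10 * p$program_cost_annual), tol = 1)
  expect_true(ts$found)
  expect_equal(ts$threshold, root_analytic, tolerance = 1e-6)
  expect_lt(abs(ts$icer_at_threshold), 1) # verified by direct model evaluation
  expect_equal(ts$direction, "at_most")
})

test_that("bisection agrees with a grid-scan oracle for the compliance threshold", {
  p <- full_params()
  ts <- threshold_search(p, "compliance", bracket = c(0.05, 0.95), tol = 1e-5)
  expect_true(ts$found)
  expect_equal(ts$direction, "at_least")
  # grid scan: locate the sign change on a fixed lattice and require the
  # bisection root to fall inside that lattice cell
  grid <- seq(0.30, 0.45, length.out = 61)
  icers <- vapply(grid, function(v)
    deterministic_icer(set_parameter(p, "compliance", v)), numeric(1))
  k <- which(diff(sign(icers)) != 0)[1]
  expect_true(ts$threshold >= grid[k] && ts$threshold <= grid[k + 1])
})

test_that("no sign change yields a no-threshold signal, not an error", {
  p <- toy_params()
  ts <- threshold_search(p, "utility.healthy", bracket = c(0.90, 0.99))
  expect_false(ts$found)
  expect_true(is.na(ts$threshold))
})

test_that("cost differentiation inflates inactive and deflates mod-high costs", {
  p <- toy_params()
  expect_equal(apply_cost_differentiation(p, 0)$costs$pa_multiplier, c(1, 1, 1))
  p5 <- apply_cost_differentiation(p, 0.05)
  expect_equal(p5$costs$pa_multiplier, c(1.05, 1, 0.95))
  expect_error(apply_cost_differentiation(p, 1.2), "delta")
  # a 1000-SGD annual state cost becomes 1050 / 1000 / 950 across PA levels
  expect_equal(1000 * p5$costs$pa_multiplier, c(1050, 1000, 950))
})

test_that("PSA means stabilise as the sample count doubles", {
  p <- toy_params()
  m1 <- run_psa(p, n_samples = 30, seed = 3)
  m2 <- run_psa(p, n_samples = 120, seed = 3)
  sd1 <- sd(m1$samples$qalys_gained)
  # standard error of the larger run should be about half that of a run a
  # quarter its size; allow generous Monte Carlo slack
  se1 <- sd1 / sqrt(30)
  se2 <- sd(m2$samples$qalys_gained) / sqrt(120)
  expect_lt(se2, se1)
  expect_lt(abs(m1$means["qalys_gained"] - m2$means["qalys_gained"]), 4 * se1)
})
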
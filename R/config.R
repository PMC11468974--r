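# Structured-text (YAML) configuration I/O. One top-level key per parameter
# group; unknown keys are errors. A machine-readable schema ships at
# inst/extdata/config-schema.json.

.CONFIG_KEYS <- c("age_bands", "pa_prevalence", "rr_incidence", "rr_mortality",
                  "utilities", "costs", "direct_indirect_ratio",
                  "intervention_pa_shift", "control_pa_shift",
                  "program_cost_annual", "compliance", "n_registered",
                  "incidence_scale", "economics", "distributions")

.matrix_to_list <- function(m) lapply(seq_len(nrow(m)), function(i) as.list(unname(m[i, ])))
.list_to_matrix <- function(lst, rown, coln, field) {
  m <- tryCatch(do.call(rbind, lapply(lst, function(r) as.numeric(unlist(r)))),
                error = function(e) NULL)
  if (is.null(m) || nrow(m) != length(rown) || ncol(m) != length(coln))
    stop("config field '", field, "': expected a ", length(rown), "x",
         length(coln), " matrix", call. = FALSE)
  dimnames(m) <- list(rown, coln)
  m
}

#' Serialise a parameter set to a config list
#'
#' @param params A `parameter_set`.
#' @return Nested plain list mirroring the YAML layout.
#' @export
as_config_list <- function(params) {
  list(
    age_bands = lapply(seq_len(nrow(params$age_bands)), function(i)
      as.list(params$age_bands[i, ])),
    pa_prevalence = setNames(.matrix_to_list(params$pa_prevalence), PA_GROUPS),
    rr_incidence = setNames(.matrix_to_list(params$rr_incidence),
                            rownames(params$rr_incidence)),
    rr_mortality = c(setNames(.matrix_to_list(params$rr_mortality), PA_GROUPS),
                     as.list(params$complication_mortality)),
    utilities = c(as.list(params$utilities$base),
                  list(pa_delta = as.numeric(params$utilities$pa_delta))),
    costs = list(inpatient = as.list(params$costs$inpatient),
                 outpatient = as.list(params$costs$outpatient),
                 inpatient_proportion = as.list(params$costs$inpatient_proportion),
                 pa_multiplier = as.numeric(params$costs$pa_multiplier)),
    direct_indirect_ratio = as.list(params$direct_indirect_ratio),
    intervention_pa_shift = .matrix_to_list(params$intervention_pa_shift),
    control_pa_shift = .matrix_to_list(params$control_pa_shift),
    program_cost_annual = params$program_cost_annual,
    compliance = params$compliance,
    n_registered = params$n_registered,
    incidence_scale = params$incidence_scale,
    economics = list(discount_rate = params$discount_rate,
                     horizon_years = params$horizon_years,
                     cycle_length = params$cycle_length,
                     wtp_grid = as.numeric(params$wtp_grid),
                     discount_timing = params$discount_timing),
    distributions = lapply(seq_len(nrow(params$distributions)), function(i)
      as.list(params$distributions[i, ]))
  )
}

#' Build a parameter set from a config list
#'
#' @param cfg Nested list as produced by [as_config_list()] or parsed from a
#'   YAML config file.
#' @return A validated `parameter_set`.
#' @export
from_config_list <- function(cfg) {
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  missing_k <- setdiff(.CONFIG_KEYS, names(cfg))
  if (length(missing_k))
    stop("missing config keys: ", paste(missing_k, collapse = ", "), call. = FALSE)

  age_bands <- do.call(rbind, lapply(cfg$age_bands, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  missing_cols <- setdiff(.AGE_BAND_COLS, names(age_bands))
  if (length(missing_cols))
    stop("config field 'age_bands': missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  age_bands <- age_bands[, .AGE_BAND_COLS]

  rr_names <- c("diabetes", "hypertension", COMPLICATIONS)
  comp_mort <- vapply(COMPLICATIONS, function(k) {
    v <- cfg$rr_mortality[[k]]
    if (is.null(v)) stop("config field 'rr_mortality.", k, "' missing", call. = FALSE)
    as.numeric(v)
  }, numeric(1))

  util_base_names <- c(PA_GROUPS, COMPLICATIONS)
  ub <- vapply(util_base_names, function(k) as.numeric(cfg$utilities[[k]]), numeric(1))

  dists <- if (length(cfg$distributions)) {
    do.call(rbind, lapply(cfg$distributions, function(r) {
      r$p2 <- if (is.null(r$p2) || is.na(r$p2)) NA_real_ else as.numeric(r$p2)
      data.frame(name = r$name, family = r$family, p1 = as.numeric(r$p1),
                 p2 = r$p2, range_rule = r$range_rule, stringsAsFactors = FALSE)
    }))
  } else empty_distributions()

  parameter_set(
    age_bands = age_bands,
    pa_prevalence = .list_to_matrix(cfg$pa_prevalence[PA_GROUPS], PA_GROUPS,
                                    PA_LEVELS, "pa_prevalence"),
    rr_incidence = .list_to_matrix(cfg$rr_incidence[rr_names], rr_names,
                                   PA_LEVELS, "rr_incidence"),
    rr_mortality = .list_to_matrix(cfg$rr_mortality[PA_GROUPS], PA_GROUPS,
                                   PA_LEVELS, "rr_mortality"),
    complication_mortality = comp_mort,
    utilities = list(base = ub, pa_delta = as.numeric(unlist(cfg$utilities$pa_delta))),
    costs = list(
      inpatient = unlist(cfg$costs$inpatient),
      outpatient = unlist(cfg$costs$outpatient),
      inpatient_proportion = unlist(cfg$costs$inpatient_proportion),
      pa_multiplier = as.numeric(unlist(cfg$costs$pa_multiplier))
    ),
    direct_indirect_ratio = unlist(cfg$direct_indirect_ratio),
    intervention_pa_shift = .list_to_matrix(cfg$intervention_pa_shift, PA_LEVELS,
                                            PA_LEVELS, "intervention_pa_shift"),
    control_pa_shift = .list_to_matrix(cfg$control_pa_shift, PA_LEVELS,
                                       PA_LEVELS, "control_pa_shift"),
    program_cost_annual = as.numeric(cfg$program_cost_annual),
    compliance = as.numeric(cfg$compliance),
    n_registered = as.numeric(cfg$n_registered),
    incidence_scale = as.numeric(cfg$incidence_scale),
    discount_rate = as.numeric(cfg$economics$discount_rate),
    horizon_years = as.integer(cfg$economics$horizon_years),
    cycle_length = as.numeric(cfg$economics$cycle_length),
    wtp_grid = as.numeric(unlist(cfg$economics$wtp_grid)),
    discount_timing = cfg$economics$discount_timing,
    distributions = dists
  )
}

#' Write a parameter set to a YAML configuration file
#'
#' @param params A `parameter_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  txt <- yaml::as.yaml(as_config_list(params), precision = 15L)
  writeLines(txt, path)
  invisible(path)
}

#' Read and validate a YAML configuration file
#'
#' Parses the file, checks for unknown/missing keys, rebuilds the
#' `parameter_set` and runs the full validation, so any domain violation is
#' reported with the offending field's name.
#'
#' @param path Config file path.
#' @return A validated `parameter_set`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  from_config_list(yaml::read_yaml(path))
}
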
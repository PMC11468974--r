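# State space: 3 disease groups x 3 physical-activity levels (9 living states),
# 2 chronic complication states without a PA level, and an absorbing dead state.

PA_LEVELS <- c("inactive", "low", "mod_high")
PA_GROUPS <- c("healthy", "diabetes", "hypertension")
COMPLICATIONS <- c("diabetes_cvd", "hypertension_stroke")

# fixed state ordering used by every 12x12 matrix in the package
.state_idx <- list(
  healthy = 1:3,
  diabetes = 4:6,
  hypertension = 7:9,
  diabetes_cvd = 10L,
  hypertension_stroke = 11L,
  dead = 12L,
  pa_blocks = list(healthy = 1:3, diabetes = 4:6, hypertension = 7:9),
  living = 1:11
)

#' Physical-activity levels
#'
#' The three PA levels used throughout the model. `inactive` is the reference
#' level for every relative risk.
#'
#' @return Character vector `c("inactive", "low", "mod_high")`.
#' @export
pa_levels <- function() PA_LEVELS

#' State names in canonical order
#'
#' @return Character vector of the 12 state labels, PA-carrying states first
#'   (group-major), then the two complication states, then `dead`.
#' @export
state_names <- function() {
  c(paste(rep(PA_GROUPS, each = 3L), rep(PA_LEVELS, times = 3L), sep = "_"),
    COMPLICATIONS, "dead")
}

#' Health-state table
#'
#' One row per state with its disease group and PA level. Complication states
#' and `dead` carry no PA level (`NA`).
#'
#' @return A data frame with columns `state`, `disease`, `pa`.
#' @export
health_states <- function() {
  data.frame(
    state = state_names(),
    disease = c(rep(PA_GROUPS, each = 3L), COMPLICATIONS, "dead"),
    pa = c(rep(PA_LEVELS, times = 3L), NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

# disease group owning each state, for cost/utility lookups
.state_group <- function() {
  c(rep(PA_GROUPS, each = 3L), "diabetes", "hypertension", "dead")
}
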
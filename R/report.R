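# Result serialisation, validation-against-observed reporting and headline
# formatting. Monetary values are stored at full precision; 3-significant-
# figure rounding is applied only at the presentation layer.

#' Round to three significant figures for headline reporting
#'
#' @param x Numeric.
#' @return Numeric rounded to 3 significant figures.
#' @export
headline_round <- function(x) signif(x, 3)

#' Format a headline number
#'
#' @param x Numeric scalar.
#' @return Character, 3 significant figures with thousands separators
#'   (e.g. `78812.3` prints as `"78,800"`).
#' @export
headline_format <- function(x) {
  format(headline_round(x), big.mark = ",", scientific = FALSE, trim = TRUE)
}

#' Compare projected with observed prevalence
#'
#' @param projected,observed Named numeric vectors over matching categories.
#' @param tolerance Absolute-difference flag threshold (default 0.05).
#' @return Data frame with `category`, `projected`, `observed`, `abs_diff`,
#'   `rel_diff`, `within_tolerance`.
#' @export
validate_against_observed <- function(projected, observed, tolerance = 0.05) {
  unmatched <- c(setdiff(names(projected), names(observed)),
                 setdiff(names(observed), names(projected)))
  if (length(unmatched))
    stop("category labels do not match: ", paste(unique(unmatched), collapse = ", "),
         call. = FALSE)
  observed <- observed[names(projected)]
  ad <- abs(projected - observed)
  data.frame(
    category = names(projected),
    projected = as.numeric(projected),
    observed = as.numeric(observed),
    abs_diff = as.numeric(ad),
    rel_diff = as.numeric(ifelse(observed != 0, ad / abs(observed), NA_real_)),
    within_tolerance = as.numeric(ad) <= tolerance,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write a results bundle to disk
#'
#' Writes `summary.csv` (one row per perspective, Table-1-shaped columns
#' including CE probabilities at each WTP grid point when a PSA is supplied),
#' `headline.txt` (3-significant-figure narrative numbers) and `metadata.txt`
#' (seed, config hash, package version). Optionally `ceac.csv` and
#' `psa_samples.csv`.
#'
#' @param incremental An `incremental_result` (deterministic base case).
#' @param dir Output directory (created if needed).
#' @param psa Optional `psa_result`.
#' @param seed Seed to record.
#' @param config_path Optional path of the config file; its MD5 is recorded.
#' @return `dir`, invisibly.
#' @export
report_results <- function(incremental, dir, psa = NULL, seed = NA,
                           config_path = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  row <- data.frame(
    perspective = incremental$perspective,
    cost_reduction = incremental$cost_reduction,
    qalys_gained = incremental$qalys_gained,
    program_cost = incremental$program_cost,
    icer = as.numeric(incremental$icer),
    classification = incremental$classification,
    stringsAsFactors = FALSE
  )
  if (!is.null(psa)) {
    row$cost_reduction_mean <- psa$means["cost_reduction"]
    row$cost_reduction_lo <- psa$ci_lo["cost_reduction"]
    row$cost_reduction_hi <- psa$ci_hi["cost_reduction"]
    for (i in seq_len(nrow(psa$ceac)))
      row[[paste0("ce_prob_wtp_", psa$ceac$wtp[i])]] <- psa$ceac$probability[i]
    write.csv(psa$samples, file.path(dir, "psa_samples.csv"), row.names = FALSE)
    write.csv(psa$ceac, file.path(dir, "ceac.csv"), row.names = FALSE)
  }
  write.csv(row, file.path(dir, "summary.csv"), row.names = FALSE)

  lab <- if (is.na(as.numeric(incremental$icer))) incremental$classification
    else if (as.numeric(incremental$icer) < 0) "cost-saving"
    else paste("SGD", headline_format(incremental$icer), "per QALY gained")
  headline <- c(
    sprintf("Cohort size: %s", headline_format(incremental$n)),
    sprintf("QALYs gained: %s", headline_format(incremental$qalys_gained)),
    sprintf("Reduction in costs (SGD): %s", headline_format(incremental$cost_reduction)),
    sprintf("Program cost (SGD): %s", headline_format(incremental$program_cost)),
    sprintf("Diabetes cases averted: %s", headline_format(incremental$cases_averted_diabetes)),
    sprintf("Hypertension cases averted: %s", headline_format(incremental$cases_averted_hypertension)),
    sprintf("Deaths averted: %s", headline_format(incremental$deaths_averted)),
    sprintf("Result: %s", lab)
  )
  writeLines(headline, file.path(dir, "headline.txt"))

  cfg_hash <- if (!is.null(config_path) && file.exists(config_path))
    unname(tools::md5sum(config_path)) else NA_character_
  meta <- c(
    sprintf("package_version: %s", as.character(utils::packageVersion("stepscea"))),
    sprintf("seed: %s", seed),
    sprintf("config_md5: %s", cfg_hash),
    sprintf("perspective: %s", incremental$perspective)
  )
  writeLines(meta, file.path(dir, "metadata.txt"))
  invisible(dir)
}

#' Write a tornado table to CSV
#'
#' @param tornado Data frame from [one_way_dsa()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tornado_csv <- function(tornado, path) {
  write.csv(tornado, path, row.names = FALSE)
  invisible(path)
}
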
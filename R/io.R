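# Reading and writing the pipeline's plain-text artifacts.

#' Write / read a county-year panel as CSV
#'
#' One row per county-year with the schema produced by [generate_panel()]
#' (births and populations by single year of age, covariates with the sparse
#' abortion-distance column blank in unobserved years, funding indicator).
#'
#' @param panel county-year data.frame.
#' @param path file path.
#' @return `write_panel_csv` returns `path` invisibly; `read_panel_csv`
#'   returns the panel data.frame.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  check_cols(df, c("county_id", "state_id", "year", "funded"), "panel CSV")
  df
}

#' Serialize simulation truth, filter reports and fits to JSON
#'
#' @param x a `sim_truth`, `filter_report`, `twfe_fit` or `csdid_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  out <- if (inherits(x, "sim_truth")) {
    list(overall_att = x$overall_att,
         overall_att_group = x$overall_att_group,
         event_effects = as.list(x$event_effects),
         treated_counties = as.list(x$treated_counties),
         seed = x$seed)
  } else if (inherits(x, "filter_report")) {
    list(excluded_counts = as.list(x$excluded_counts),
         excluded_ids = x$excluded_ids,
         n_input = x$n_input, n_remaining = x$n_remaining)
  } else if (inherits(x, "twfe_fit")) {
    list(model = x$spec$model_id, estimate = x$estimate, se = x$se,
         ci = x$ci, percent = x$percent, coefficients = as.list(x$coefficients),
         n_obs = x$n_obs, n_clusters = x$n_clusters, dropped = x$dropped,
         r2_within = x$r2_within)
  } else if (inherits(x, "csdid_result")) {
    list(mode = x$mode,
         overall = list(att = x$overall$att, se = x$overall$se,
                        ci = x$overall$ci,
                        percent = interpret_as_percent(x$overall$att)),
         event_study = x$event_study,
         pretrend = x$pretrend, reps = x$reps, seed = x$seed)
  } else {
    unclass(x)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
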
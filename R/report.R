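#' Configuration for an end-to-end pipeline run
#'
#' @param sim a [sim_config()] describing the data-generating process.
#' @param age_mode passed to [build_analysis_rows()].
#' @param estimators subset of `model1`, `model2`, `model3`,
#'   `cs_unconditional`, `cs_conditional`.
#' @param covariates covariate columns used by models 2-3 and the
#'   conditional CS estimator.
#' @param reps multiplier-bootstrap replications for the CS estimators.
#' @param boot_seed bootstrap seed (simulation uses `sim$seed`).
#' @param pre_window pre-trend Wald window, see [fit_csdid()].
#' @param out_dir optional directory for artifacts (comparison table,
#'   event-study CSV, filter report, manifest, log).
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       age_mode = c("aggregate", "age_specific"),
                       estimators = c("model1", "model2", "model3",
                                      "cs_unconditional", "cs_conditional"),
                       covariates = covariate_cols(),
                       reps = 999L,
                       boot_seed = sim$seed + 1L,
                       pre_window = 5,
                       out_dir = NULL) {
  age_mode <- match.arg(age_mode)
  known <- c("model1", "model2", "model3", "cs_unconditional",
             "cs_conditional")
  bad <- setdiff(estimators, known)
  if (length(bad)) stop_bad_arg("unknown estimator(s): ",
                                paste(bad, collapse = ", "))
  if (!length(estimators)) stop_bad_arg("estimator list must be non-empty")
  structure(list(sim = sim, age_mode = age_mode, estimators = estimators,
                 covariates = covariates,
                 reps = as.integer(reps), boot_seed = as.integer(boot_seed),
                 pre_window = pre_window, out_dir = out_dir),
            class = "run_config")
}

fit_one_estimator <- function(est, rows, config) {
  cv <- config$covariates %||% covariate_cols()
  switch(est,
    model1 = fit_twfe(rows, twfe_spec(1L)),
    model2 = fit_twfe(rows, twfe_spec(2L, covariates = cv)),
    model3 = fit_twfe(rows, twfe_spec(3L, covariates = cv)),
    cs_unconditional = fit_csdid(rows, mode = "unconditional",
                                 reps = config$reps, seed = config$boot_seed,
                                 pre_window = config$pre_window),
    cs_conditional = fit_csdid(rows, mode = "conditional", covariates = cv,
                               reps = config$reps, seed = config$boot_seed,
                               pre_window = config$pre_window))
}

comparison_row <- function(est, fit, n_counties) {
  if (inherits(fit, "twfe_fit")) {
    data.frame(estimator = est, estimate = fit$estimate, se = fit$se,
               ci_lo = fit$ci[1], ci_hi = fit$ci[2],
               pct_exact = fit$percent$exact, pct_rough = fit$percent$rough,
               n_obs = fit$n_obs, n_counties = fit$n_clusters)
  } else {
    pc <- interpret_as_percent(fit$overall$att)
    data.frame(estimator = est, estimate = fit$overall$att,
               se = fit$overall$se,
               ci_lo = fit$overall$ci[1], ci_hi = fit$overall$ci[2],
               pct_exact = pc$exact, pct_rough = pc$rough,
               n_obs = NA_integer_, n_counties = n_counties)
  }
}

#' Run the full simulate - build - estimate pipeline
#'
#' Generates a synthetic panel, applies the sample filters, builds analysis
#' rows, fits the requested estimators (three fixed-effects models and the
#' unconditional/conditional group-time ATT estimators) and assembles a
#' comparison table of the treatment estimates on the log and percent scales.
#' Deterministic given the config seeds. With `out_dir` set, writes the
#' comparison table (CSV + JSON), the event-study table(s), the filter
#' report, the simulation truth, a manifest and a stage log.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result`: `comparison` (one row per
#'   estimator), `fits` (named list), `filter_report`, `truth`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- "simulate"
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  result <- tryCatch({
    sp <- generate_panel(config$sim)
    note("simulate: %d rows, %d counties", nrow(sp$panel),
         length(unique(sp$panel$county_id)))

    stage <- "filter"
    crit <- filter_criteria(main_cohort_years =
                              vapply(config$sim$cohorts, `[`, 0L, 1))
    filt <- apply_sample_filters(sp$panel, criteria = crit)
    note("filter: %d -> %d counties (%s)", filt$report$n_input,
         filt$report$n_remaining,
         paste(names(filt$report$excluded_counts),
               filt$report$excluded_counts, sep = "=", collapse = ", "))

    stage <- "build"
    rows <- build_analysis_rows(filt$records, age_mode = config$age_mode)
    note("build: %d analysis rows, years %d-%d", nrow(rows),
         min(rows$year), max(rows$year))

    fits <- list()
    for (est in config$estimators) {
      stage <- est
      fits[[est]] <- fit_one_estimator(est, rows, config)
      if (inherits(fits[[est]], "twfe_fit") && length(fits[[est]]$dropped)) {
        note("%s: dropped collinear columns %s", est,
             paste(fits[[est]]$dropped, collapse = ", "))
      }
      note("%s: estimate %.4f", est,
           if (inherits(fits[[est]], "twfe_fit")) fits[[est]]$estimate
           else fits[[est]]$overall$att)
    }
    n_counties <- filt$report$n_remaining
    comparison <- do.call(rbind, Map(comparison_row, names(fits), fits,
                                     n_counties))
    rownames(comparison) <- NULL
    list(comparison = comparison, fits = fits,
         filter_report = filt$report, truth = sp$truth, log = log_lines)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result$config <- config
  class(result) <- "pipeline_result"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    utils::write.csv(result$comparison, p("comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(result$comparison, p("comparison.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (est in names(result$fits)) {
      f <- result$fits[[est]]
      if (inherits(f, "csdid_result")) {
        utils::write.csv(f$event_study, p(sprintf("event_study_%s.csv", est)),
                         row.names = FALSE)
        write_result_json(f, p(sprintf("%s.json", est)))
      } else {
        write_result_json(f, p(sprintf("%s.json", est)))
      }
    }
    write_result_json(result$filter_report, p("filter_report.json"))
    write_result_json(result$truth, p("sim_truth.json"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("countydid")),
      r_version = R.version.string,
      sim_seed = config$sim$seed,
      boot_seed = config$boot_seed,
      estimators = config$estimators,
      reps = config$reps,
      n_counties = sum(config$sim$counties_per_state),
      years = config$sim$years)
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    writeLines(result$log, p("run.log"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$comparison, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Monte Carlo validation of the estimators
#'
#' Repeats the simulate - build - fit pipeline with seeds `sim$seed + rep`,
#' and summarizes each requested estimator's bias against its matching true
#' estimand (the treated-cell-weighted true ATT for the fixed-effects models,
#' the group-size-weighted true ATT for the CS aggregations), the empirical
#' SD, the mean reported SE, and 95% CI coverage. When a CS estimator is
#' included, the pre-trend Wald p-value is recorded per replication.
#'
#' @param config a [run_config()]; bootstrap bands are skipped (they are not
#'   needed for overall-ATT coverage), so `reps` is ignored.
#' @param n_reps number of replications (>= 2).
#' @return list of class `mc_study`: `summary` data.frame and the per-rep
#'   `draws`.
#' @export
monte_carlo_study <- function(config = run_config(), n_reps = 100L) {
  stopifnot(inherits(config, "run_config"))
  if (n_reps < 2L) stop_bad_arg("`n_reps` must be >= 2")
  ests <- config$estimators
  draws <- vector("list", n_reps)
  for (rep in seq_len(n_reps)) {
    sim_r <- config$sim
    sim_r$seed <- config$sim$seed + rep
    sp <- generate_panel(sim_r)
    crit <- filter_criteria(main_cohort_years =
                              vapply(config$sim$cohorts, `[`, 0L, 1))
    rows <- build_analysis_rows(apply_sample_filters(sp$panel,
                                                     criteria = crit)$records,
                                age_mode = config$age_mode)
    rec <- list(rep = rep,
                truth_cell = sp$truth$overall_att,
                truth_group = sp$truth$overall_att_group)
    for (est in ests) {
      if (startsWith(est, "model")) {
        cv <- config$covariates %||% covariate_cols()
        f <- fit_twfe(rows, twfe_spec(as.integer(substring(est, 6)),
                                      covariates = cv))
        rec[[paste0(est, "_est")]] <- f$estimate
        rec[[paste0(est, "_se")]] <- f$se
        rec[[paste0(est, "_cover")]] <-
          f$ci[1] <= sp$truth$overall_att && sp$truth$overall_att <= f$ci[2]
      } else {
        mode <- sub("cs_", "", est)
        ag <- att_gt(rows, mode = mode,
                     covariates = config$covariates %||% covariate_cols())
        ov <- aggregate_overall(ag)
        rec[[paste0(est, "_est")]] <- ov$att
        rec[[paste0(est, "_se")]] <- ov$se
        rec[[paste0(est, "_cover")]] <-
          ov$ci[1] <= sp$truth$overall_att_group &&
          sp$truth$overall_att_group <= ov$ci[2]
        es <- aggregate_event_study(ag)
        pre <- which(es$table$event < 0 &
                       es$table$event >= -config$pre_window)
        if (length(pre)) {
          Vp <- crossprod(es$inf[, pre, drop = FALSE]) / es$n^2
          rec[[paste0(est, "_pretrend_p")]] <-
            pretrend_wald(es$table$estimate[pre], Vp)$p_value
        }
      }
    }
    draws[[rep]] <- as.data.frame(rec)
  }
  draws <- do.call(rbind, draws)
  summ <- do.call(rbind, lapply(ests, function(est) {
    tr <- if (startsWith(est, "model")) draws$truth_cell else draws$truth_group
    e <- draws[[paste0(est, "_est")]]
    data.frame(estimator = est,
               true = mean(tr),
               mean_est = mean(e),
               bias = mean(e - tr),
               sd_est = stats::sd(e),
               mean_se = mean(draws[[paste0(est, "_se")]]),
               coverage = mean(draws[[paste0(est, "_cover")]]))
  }))
  structure(list(summary = summ, draws = draws, n_reps = n_reps,
                 config = config),
            class = "mc_study")
}

#' @export
print.mc_study <- function(x, ...) {
  cat(sprintf("<mc_study> %d replications\n", x$n_reps))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
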
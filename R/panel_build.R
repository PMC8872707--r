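#' Birth rate per 1,000 women
#'
#' @param births number of births (count, vectorized).
#' @param population number of women at risk (count, vectorized).
#' @return births per 1,000 population.
#' @examples
#' compute_rate(5, 1000)  # 5 per 1,000
#' @export
compute_rate <- function(births, population) {
  if (any(population <= 0)) {
    stop_bad_arg("population must be positive (zero-population counties are ",
                 "excluded by the sample filters)")
  }
  if (any(births < 0)) stop_bad_arg("births must be non-negative")
  1000 * births / population
}

#' Outcome transform log(1 + R)
#'
#' The log of one plus the rate keeps zero rates finite and lets regression
#' coefficients be read approximately as percent changes in the rate.
#'
#' @param rate rate per 1,000 (non-negative, vectorized).
#' @return log(1 + rate).
#' @export
transform_outcome <- function(rate) {
  if (any(rate < 0)) stop_bad_arg("rate must be non-negative")
  log1p(rate)
}

#' Linear interpolation/extrapolation of a sparsely observed covariate
#'
#' Linear interpolation between observed years; outside the observed range,
#' linear extrapolation at the slope of the nearest observed segment (the
#' first segment before the first knot, the last segment after the last).
#' Exact at observed years.
#'
#' @param observations named numeric vector mapping observed year -> value
#'   (at least two observation years).
#' @param target_year year(s) at which to evaluate.
#' @return interpolated value(s).
#' @examples
#' interpolate_sparse_covariate(c(`2000` = 10, `2011` = 21), 2005)  # 15
#' @export
interpolate_sparse_covariate <- function(observations, target_year) {
  yrs <- as.numeric(names(observations))
  if (length(observations) < 2L || anyNA(yrs)) {
    stop_bad_arg("need >= 2 year-named observations to interpolate")
  }
  o <- order(yrs)
  yrs <- yrs[o]; vals <- as.numeric(observations[o])
  k <- length(yrs)
  slope_lo <- (vals[2] - vals[1]) / (yrs[2] - yrs[1])
  slope_hi <- (vals[k] - vals[k - 1]) / (yrs[k] - yrs[k - 1])
  out <- stats::approx(yrs, vals, xout = target_year, rule = 1)$y
  lo <- target_year < yrs[1]
  hi <- target_year > yrs[k]
  out[lo] <- vals[1] + slope_lo * (target_year[lo] - yrs[1])
  out[hi] <- vals[k] + slope_hi * (target_year[hi] - yrs[k])
  out
}

#' Filter criteria for sample construction
#'
#' @param main_cohort_years funding start years that define the main award
#'   cohorts; funded counties outside these are dropped (rule 4).
#' @param excluded_states state ids dropped wholesale (rule 5; the analog of
#'   excluding Hawaii, whose natality data were not county-disaggregated
#'   early in the period).
#' @param reporting_change_counties county ids flagged as having changed
#'   reporting area (folded into rule 1; the flag is an input, it has no
#'   internal operational definition).
#' @param fill_sparse names of covariates filled by per-county linear
#'   interpolation/extrapolation before the missing-covariate rule runs.
#' @return list of class `filter_criteria`.
#' @export
filter_criteria <- function(main_cohort_years = c(2010L, 2015L),
                            excluded_states = character(),
                            reporting_change_counties = character(),
                            fill_sparse = "abortion_distance") {
  structure(list(main_cohort_years = as.integer(main_cohort_years),
                 excluded_states = excluded_states,
                 reporting_change_counties = reporting_change_counties,
                 fill_sparse = fill_sparse),
            class = "filter_criteria")
}

#' Apply the sample-exclusion rules to a county-year panel
#'
#' Drops counties, in order: (1) any year with zero female population aged
#' 14-19, or a flagged reporting-area change; (2) prior abstinence-only
#' funding; (3) missing at least one year of any time-varying covariate
#' (after sparse covariates are filled by interpolation); (4) funded but
#' outside the main award cohorts; (5) in an excluded state. A county failing
#' several rules is attributed to the first, so the per-rule counts are
#' disjoint.
#'
#' @param records county-year data.frame with the panel schema (see
#'   [generate_panel()]).
#' @param funding_history optional named vector county id -> first funding
#'   year (defaults to the first year with `funded == 1` in `records`).
#' @param abstinence_counties county ids with prior abstinence-only funding.
#' @param criteria a [filter_criteria()].
#' @return list with `records` (filtered, sparse covariates filled) and
#'   `report` (class `filter_report`: per-rule excluded counts and ids,
#'   remaining county count).
#' @export
apply_sample_filters <- function(records,
                                 funding_history = NULL,
                                 abstinence_counties = character(),
                                 criteria = filter_criteria()) {
  check_cols(records, c("county_id", "state_id", "year", pop_cols(), "funded"),
             "records")
  ids <- unique(records$county_id)

  # fill sparse covariates county-by-county before the missing-data rule
  for (cv in intersect(criteria$fill_sparse, names(records))) {
    sp <- split(seq_len(nrow(records)), records$county_id)
    for (rows in sp) {
      v <- records[[cv]][rows]
      obs <- !is.na(v)
      if (any(!obs) && sum(obs) >= 2L) {
        records[[cv]][rows[!obs]] <- interpolate_sparse_covariate(
          stats::setNames(v[obs], records$year[rows][obs]),
          records$year[rows][!obs])
      }
    }
  }

  if (is.null(funding_history)) {
    f <- records[records$funded == 1, c("county_id", "year")]
    funding_history <- if (nrow(f)) {
      vapply(split(f$year, f$county_id), min, 0L)
    } else stats::setNames(integer(), character())
  }

  pop_tot <- rowSums(records[, pop_cols(), drop = FALSE])
  zero_ids <- unique(records$county_id[pop_tot <= 0])
  rule1 <- union(zero_ids, intersect(criteria$reporting_change_counties, ids))
  rule2 <- intersect(abstinence_counties, ids)
  cov_present <- intersect(covariate_cols(), names(records))
  has_missing <- rowSums(is.na(records[, cov_present, drop = FALSE])) > 0
  rule3 <- unique(records$county_id[has_missing])
  funded_ids <- names(funding_history)
  rule4 <- funded_ids[!(funding_history %in% criteria$main_cohort_years)]
  state_of <- records$state_id[!duplicated(records$county_id)]
  names(state_of) <- records$county_id[!duplicated(records$county_id)]
  rule5 <- ids[state_of[ids] %in% criteria$excluded_states]

  rules <- list(zero_pop_or_reporting = rule1,
                abstinence_funded = rule2,
                missing_covariate = rule3,
                off_cohort_funded = rule4,
                excluded_state = rule5)
  dropped <- character()
  excluded <- lapply(rules, function(r) {
    r <- setdiff(intersect(r, ids), dropped)
    dropped <<- union(dropped, r)
    r
  })
  keep <- !(records$county_id %in% dropped)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) warning("all counties excluded by the sample filters")
  report <- structure(list(
    excluded_ids = excluded,
    excluded_counts = vapply(excluded, length, 0L),
    n_input = length(ids),
    n_remaining = length(ids) - length(dropped)
  ), class = "filter_report")
  list(records = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  for (nm in names(x$excluded_counts)) {
    cat(sprintf("  %-22s %d\n", nm, x$excluded_counts[[nm]]))
  }
  cat(sprintf("  remaining counties     %d of %d\n", x$n_remaining, x$n_input))
  invisible(x)
}

#' Build model-ready analysis rows from a county-year panel
#'
#' Computes the birth rate R per 1,000 (pooled over ages 14-19 or one row per
#' single year of age), the log(1 + R) outcome, and the treatment indicator
#' and covariates lagged by `lag` years within county (the lag reflects the
#' time from conception to birth). The first `lag` panel years are dropped
#' because no lagged values exist for them. A county first funded in calendar
#' year g therefore first contributes a treated row in year g + lag.
#'
#' @param records balanced county-year panel (schema of [generate_panel()];
#'   sparse covariates should already be filled, see
#'   [apply_sample_filters()]).
#' @param age_mode `"aggregate"` (one pooled 14-19 rate per county-year, the
#'   default) or `"age_specific"` (stacked single-year-of-age rows).
#' @param lag years by which treatment and covariates are lagged (default 1;
#'   0 gives the no-lag degenerate case).
#' @param weight_by_population if `TRUE`, adds a `weight` column equal to the
#'   county-year female population 14-19 (used by [fit_twfe()]'s `weights`).
#' @return data.frame of analysis rows: `county_id`, `state_id`, `year`,
#'   optional `age`, `outcome` (log(1+R)), `treat` (lagged funding), lagged
#'   covariates under their own names, and `cohort` (first treated analysis
#'   year, `NA` for never-treated).
#' @export
build_analysis_rows <- function(records,
                                age_mode = c("aggregate", "age_specific"),
                                lag = 1L,
                                weight_by_population = FALSE) {
  age_mode <- match.arg(age_mode)
  check_cols(records, c("county_id", "state_id", "year", birth_cols(),
                        pop_cols(), "funded"), "records")
  lag <- as.integer(lag)
  if (lag < 0L) stop_bad_arg("`lag` must be >= 0")

  years <- sort(unique(records$year))
  tab <- table(records$county_id)
  if (any(tab != length(years)) ||
      nrow(records) != length(tab) * length(years)) {
    bad <- names(tab)[tab != length(years)]
    stop_bad_arg("panel is not balanced; offending counties: ",
                 paste(utils::head(bad, 10), collapse = ", "),
                 if (length(bad) > 10) ", ...")
  }
  records <- records[order(records$county_id, records$year), , drop = FALSE]
  n_years <- length(years)
  C <- length(tab)

  covs <- intersect(covariate_cols(), names(records))
  # lag within county: row i takes the value from row i - lag of the same
  # county; ordering guarantees contiguous county blocks
  lag_vec <- function(v) {
    m <- matrix(v, nrow = n_years)
    if (lag == 0L) return(v)
    m <- rbind(matrix(NA, lag, C), m[seq_len(n_years - lag), , drop = FALSE])
    as.vector(m)
  }

  base <- records[, c("county_id", "state_id", "year")]
  base$treat <- lag_vec(records$funded)
  for (cv in covs) base[[cv]] <- lag_vec(records[[cv]])
  keep <- records$year >= years[1] + lag

  pool_pop <- rowSums(records[, pop_cols(), drop = FALSE])
  if (age_mode == "aggregate") {
    pool_births <- rowSums(records[, birth_cols(), drop = FALSE])
    base$outcome <- transform_outcome(compute_rate(pool_births, pool_pop))
    if (weight_by_population) base$weight <- pool_pop
    out <- base[keep, , drop = FALSE]
  } else {
    pieces <- lapply(seq_along(AGE_RANGE), function(a) {
      b <- base
      b$age <- AGE_RANGE[a]
      b$outcome <- transform_outcome(compute_rate(
        records[[birth_cols()[a]]], records[[pop_cols()[a]]]))
      if (weight_by_population) b$weight <- records[[pop_cols()[a]]]
      b[keep, , drop = FALSE]
    })
    out <- do.call(rbind, pieces)
    out <- out[order(out$county_id, out$year, out$age), , drop = FALSE]
  }

  # first analysis year in which the county appears treated
  ft <- out$year; ft[out$treat != 1 | is.na(out$treat)] <- NA_integer_
  first_treat <- tapply(ft, out$county_id, function(v) {
    if (all(is.na(v))) NA_integer_ else min(v, na.rm = TRUE)
  })
  out$cohort <- as.integer(first_treat[out$county_id])
  rownames(out) <- NULL
  out
}
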
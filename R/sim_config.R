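#' Default treatment-effect path by time since (lagged) treatment
#'
#' Effects are on the log(1 + R) scale, indexed by event time 0, 1, 2, ...
#' (years since a county's first treated analysis year). The default ramps
#' from about -1.5% in the first treated year to about -7% in the fifth and
#' stays flat thereafter, the qualitative shape reported for comprehensive
#' sex-education funding effects on county teen birth rates.
#'
#' @param e0 effect at event time 0.
#' @param e4 effect at event time 4.
#' @param max_event last event time carried (flat after the ramp).
#' @return Named numeric vector (names are event times as characters).
#' @export
default_effect_path <- function(e0 = -0.015, e4 = -0.07, max_event = 7) {
  ramp <- seq(e0, e4, length.out = 5)
  path <- c(ramp, rep(e4, max(0L, max_event - 4L)))
  names(path) <- as.character(0:max_event)
  path
}

#' Configuration for the synthetic county-year panel generator
#'
#' Defines a data-generating process with the structure the estimating
#' equations assume: additive county intercepts, state-year shocks, optional
#' county-specific linear trends, covariate effects, and a treatment effect on
#' the log(1 + R) scale that ramps with time since treatment. Defaults match
#' the study conditions of the motivating analysis: years 1996-2017, 2,927
#' counties in 49 states, and staggered two-cohort adoption (36 counties
#' funded from 2010, a further 19 from 2015).
#'
#' @param n_states number of states.
#' @param counties_per_state scalar or length-`n_states` vector of county
#'   counts; the default (48 states of 60 counties plus one of 47) yields
#'   exactly 2,927 counties.
#' @param years length-2 inclusive calendar-year range.
#' @param cohorts list of `c(first_funding_year, n_treated_counties)` pairs.
#' @param effect_path named numeric vector mapping event time (years since the
#'   first treated analysis year, i.e. funding year + 1) to the additive
#'   effect on log(1 + R). Must cover every event time realized in the panel.
#' @param sigma_county sd of county intercepts (log scale).
#' @param sigma_stateyear sd of state-year shocks.
#' @param sigma_trend sd of county-specific linear trend slopes (per year).
#' @param sigma_noise sd of the idiosyncratic county-year error. The default
#'   0.08 reproduces event-study standard errors of roughly 1.5-2% at the
#'   default cohort sizes, the scale of uncertainty reported for the real
#'   county panel.
#' @param covariate_effects named coefficients on the (lagged) covariates in
#'   the outcome equation.
#' @param outcome_mode `"gaussian_rate"` generates log(1 + R) from the linear
#'   model exactly and stores real-valued expected births, making model-based
#'   recovery exact; `"poisson_births"` draws integer births per single year
#'   of age as Poisson counts with mean pop * R / 1000.
#' @param base_rate baseline births per 1,000 women (overall teen-rate scale).
#' @param secular_trend common per-year drift in log(1 + R) (absorbed by
#'   state-year fixed effects; default mimics the national decline in teen
#'   births over the period).
#' @param trend_adoption_shift mean added to the trend slopes of treated
#'   counties; a nonzero value makes adoption correlate with county trends,
#'   the confounding pattern that biases static two-way fixed-effects fits.
#' @param distance_knots calendar years in which the abortion-distance
#'   covariate is observed (blank elsewhere, to be filled by interpolation).
#' @param seed integer seed; the generator is byte-deterministic given the
#'   config and seed.
#' @return An object of class `sim_config`.
#' @seealso [generate_panel()]
#' @export
sim_config <- function(n_states = 49,
                       counties_per_state = c(rep(60L, 48L), 47L),
                       years = c(1996L, 2017L),
                       cohorts = list(c(2010L, 36L), c(2015L, 19L)),
                       effect_path = default_effect_path(),
                       sigma_county = 0.35,
                       sigma_stateyear = 0.04,
                       sigma_trend = 0.008,
                       sigma_noise = 0.08,
                       covariate_effects = c(
                         abortion_distance = 5e-4,
                         unemployment = 0.008,
                         median_income = -2e-6,
                         poverty = 0.004,
                         pct_16_19 = 0.002,
                         pct_white = 0,
                         pct_black = 0.002,
                         pct_hispanic = 0.001),
                       outcome_mode = c("gaussian_rate", "poisson_births"),
                       base_rate = 40,
                       secular_trend = -0.02,
                       trend_adoption_shift = 0,
                       distance_knots = c(2000L, 2011L, 2014L),
                       seed = 1L) {
  outcome_mode <- match.arg(outcome_mode)
  check_number(n_states, "n_states", lower = 1)
  if (length(counties_per_state) == 1L) {
    counties_per_state <- rep(as.integer(counties_per_state), n_states)
  }
  if (length(counties_per_state) != n_states) {
    stop_bad_arg("`counties_per_state` must be a scalar or length n_states")
  }
  if (any(counties_per_state < 1)) stop_bad_arg("each state needs >= 1 county")
  if (length(years) != 2L || years[2] <= years[1]) {
    stop_bad_arg("`years` must be an increasing length-2 range")
  }
  for (s in c("sigma_county", "sigma_stateyear", "sigma_trend", "sigma_noise")) {
    check_number(get(s), s, lower = 0)
  }
  check_number(base_rate, "base_rate", lower = 0)
  if (!is.numeric(seed) || length(seed) != 1L || abs(seed) >= 2^31 - 10) {
    stop_bad_arg("`seed` must be a single integer below 2^31")
  }
  cohorts <- lapply(cohorts, function(co) {
    if (length(co) != 2L) stop_bad_arg("each cohort is c(first_funding_year, n)")
    co <- as.integer(co)
    if (co[1] < years[1] || co[1] > years[2]) {
      stop_bad_arg("cohort funding years must lie inside the year range")
    }
    if (co[2] < 0) stop_bad_arg("cohort sizes must be non-negative")
    co
  })
  n_counties <- sum(counties_per_state)
  if (length(cohorts) && sum(vapply(cohorts, `[`, 0L, 2)) > n_counties) {
    stop_bad_arg("sum of treated cohort sizes exceeds the number of counties")
  }
  if (is.null(names(effect_path)) ||
      anyNA(suppressWarnings(as.integer(names(effect_path))))) {
    stop_bad_arg("`effect_path` must be a named vector keyed by event time")
  }
  covs <- covariate_cols()
  eff <- stats::setNames(numeric(length(covs)), covs)
  if (length(covariate_effects)) {
    bad <- setdiff(names(covariate_effects), covs)
    if (length(bad)) stop_bad_arg("unknown covariate(s): ", paste(bad, collapse = ", "))
    eff[names(covariate_effects)] <- covariate_effects
  }
  structure(list(
    n_states = as.integer(n_states),
    counties_per_state = as.integer(counties_per_state),
    years = as.integer(years),
    cohorts = cohorts,
    effect_path = effect_path,
    sigma_county = sigma_county,
    sigma_stateyear = sigma_stateyear,
    sigma_trend = sigma_trend,
    sigma_noise = sigma_noise,
    covariate_effects = eff,
    outcome_mode = outcome_mode,
    base_rate = base_rate,
    secular_trend = secular_trend,
    trend_adoption_shift = trend_adoption_shift,
    distance_knots = as.integer(distance_knots),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  yrs <- x$years
  cat("<sim_config>\n")
  cat(sprintf("  counties: %d in %d states; years %d-%d\n",
              sum(x$counties_per_state), x$n_states, yrs[1], yrs[2]))
  for (co in x$cohorts) {
    cat(sprintf("  cohort: %d counties first funded %d\n", co[2], co[1]))
  }
  cat(sprintf("  outcome: %s, base rate %.1f per 1,000\n",
              x$outcome_mode, x$base_rate))
  cat(sprintf("  effect path (event 0..%s): %s\n",
              names(x$effect_path)[length(x$effect_path)],
              paste(sprintf("%.3f", x$effect_path), collapse = " ")))
  invisible(x)
}
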
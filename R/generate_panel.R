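#' Assign counties to staggered funding cohorts
#'
#' Randomly (but reproducibly) selects which counties belong to each funding
#' cohort; counties not selected form the never-funded residual set.
#'
#' @param county_ids character vector of unique county identifiers.
#' @param cohorts list of `c(first_funding_year, n)` pairs.
#' @param seed integer seed; the same inputs and seed give the same assignment.
#' @return Named integer vector mapping county id to first funding year
#'   (`NA` for never-funded counties).
#' @export
assign_cohorts <- function(county_ids, cohorts, seed = 1L) {
  if (anyDuplicated(county_ids)) stop_bad_arg("duplicate county ids")
  n_needed <- if (length(cohorts)) sum(vapply(cohorts, `[`, 0, 2)) else 0
  if (n_needed > length(county_ids)) {
    stop_bad_arg("infeasible cohort sizes: more treated counties than counties")
  }
  out <- stats::setNames(rep(NA_integer_, length(county_ids)), county_ids)
  shuffled <- with_seed(seed, sample(county_ids))
  pos <- 1L
  for (co in cohorts) {
    n <- as.integer(co[2])
    if (n > 0L) {
      out[shuffled[pos:(pos + n - 1L)]] <- as.integer(co[1])
      pos <- pos + n
    }
  }
  out
}

effect_at <- function(path, e) {
  key <- as.character(e)
  miss <- setdiff(key, names(path))
  if (length(miss)) {
    stop_bad_arg("effect_path is missing realized event time(s): ",
                 paste(miss, collapse = ", "))
  }
  unname(path[key])
}

# AR(1) deviations around zero, one column per year (stationary start).
ar1_matrix <- function(n, n_years, phi, sd_innov) {
  dev <- matrix(0, n, n_years)
  dev[, 1] <- stats::rnorm(n, 0, sd_innov / sqrt(1 - phi^2))
  for (j in seq_len(n_years - 1L)) {
    dev[, j + 1L] <- phi * dev[, j] + stats::rnorm(n, 0, sd_innov)
  }
  dev
}

#' Generate a synthetic county-year panel with known ground truth
#'
#' Produces a balanced county-year panel with the statistical structure the
#' fixed-effects and group-time ATT estimators assume: county intercepts,
#' state-year shocks, a common secular decline, optional county-specific
#' linear trends, persistent AR(1) covariates with state-level means, an
#' abortion-distance covariate that drifts linearly within county and is
#' observed only in sparse knot years, and staggered absorbing adoption of
#' funding. The treatment effect enters log(1 + R) one year after the funding
#' year (event time 0 = funding year + 1), mirroring the one-year conception
#' lag the downstream models assume. The outcome equation uses covariates at
#' year t - 1, so covariate-adjusted models with one-year-lagged covariates
#' are correctly specified.
#'
#' @param config a [sim_config()].
#' @return Object of class `sim_panel`: a list with `panel` (data.frame, one
#'   row per county-year with births and female population by single year of
#'   age 14-19, covariates and the funding indicator) and `truth`
#'   (`sim_truth`: true overall ATTs, event-time effects, treated county ids,
#'   county intercepts and trend slopes, seed).
#' @examples
#' sp <- generate_panel(sim_config(n_states = 2, counties_per_state = 5,
#'                                 years = c(2005, 2012),
#'                                 cohorts = list(c(2008, 3)), seed = 7))
#' head(sp$panel[, 1:6])
#' sp$truth$overall_att
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  y0 <- config$years[1]; y1 <- config$years[2]
  years <- y0:y1
  n_years <- length(years)
  C <- sum(config$counties_per_state)
  county_id <- sprintf("c%04d", seq_len(C))
  state_id <- rep(sprintf("s%02d", seq_len(config$n_states)),
                  times = config$counties_per_state)
  state_idx <- rep(seq_len(config$n_states), times = config$counties_per_state)

  cohort_of <- assign_cohorts(county_id, config$cohorts, seed = config$seed + 1L)
  treated <- !is.na(cohort_of)

  sim <- with_seed(config$seed, {
    S <- config$n_states
    # county intercepts and trend slopes (confounding shifts treated slopes)
    alpha <- stats::rnorm(C, 0, config$sigma_county)
    slope <- stats::rnorm(C, 0, config$sigma_trend) +
      config$trend_adoption_shift * treated
    # state-year shocks
    phi_sy <- matrix(stats::rnorm(S * n_years, 0, config$sigma_stateyear),
                     S, n_years)

    # populations by single year of age: county size x age profile x small
    # annual multiplicative noise
    size <- stats::rlnorm(C, log(250), 0.9)
    base_age <- size * exp(matrix(stats::rnorm(C * 6, 0, 0.05), C, 6))
    pop <- array(0, dim = c(C, 6, n_years))
    for (j in seq_len(n_years)) {
      pop[, , j] <- pmax(5, round(base_age * exp(matrix(
        stats::rnorm(C * 6, 0, 0.02), C, 6))))
    }

    # covariates over y0-1 .. y1 (one pre-year so lagged values exist for y0)
    ncy <- n_years + 1L
    st <- function(mu, sd, lo) pmax(lo, stats::rnorm(S, mu, sd))
    unemp <- st(5.5, 1.0, 2)[state_idx] + ar1_matrix(C, ncy, 0.85, 0.4)
    unemp <- pmax(unemp, 0.5)
    income <- st(52000, 8000, 30000)[state_idx] + ar1_matrix(C, ncy, 0.9, 1200)
    poverty <- pmax(st(14, 3, 4)[state_idx] + ar1_matrix(C, ncy, 0.85, 0.5), 1)
    p1619 <- pmin(pmax(stats::rnorm(C, 66.7, 1.5) +
                         ar1_matrix(C, ncy, 0.8, 0.3), 0), 100)
    white <- pmin(pmax(stats::runif(S, 55, 90)[state_idx] +
                         stats::rnorm(C, 0, 6) +
                         ar1_matrix(C, ncy, 0.9, 0.3), 0), 100)
    black <- pmin(pmax(stats::runif(S, 2, 25)[state_idx] +
                         stats::rnorm(C, 0, 4) +
                         ar1_matrix(C, ncy, 0.9, 0.25), 0), 100)
    hisp <- pmin(pmax(stats::runif(S, 3, 25)[state_idx] +
                        stats::rnorm(C, 0, 4) +
                        ar1_matrix(C, ncy, 0.9, 0.25), 0), 100)
    # abortion distance: piecewise linear in year within county with a slope
    # change at the middle knot year, so the analysis-side linear
    # interpolation/extrapolation from the knot years recovers it exactly
    dist0 <- 25 + stats::rgamma(C, shape = 2, scale = 20)
    dslope1 <- stats::rnorm(C, 0, 0.4)
    dslope2 <- stats::rnorm(C, 0, 0.4)
    dknot <- config$distance_knots[min(2L, length(config$distance_knots))]
    noise <- matrix(stats::rnorm(C * n_years, 0, config$sigma_noise), C, n_years)

    dist_at <- function(yr) {
      dist0 + ifelse(rep(yr, C) <= dknot, dslope1, dslope2) * (yr - dknot)
    }

    # outcome: log(1 + R) linear index per county-year
    eff <- config$covariate_effects
    log1R <- matrix(0, C, n_years)
    effect_mat <- matrix(0, C, n_years)
    for (j in seq_len(n_years)) {
      yr <- years[j]
      idx <- log1p(config$base_rate) +
        config$secular_trend * (yr - y0) +
        alpha + phi_sy[cbind(state_idx, j)] + slope * (yr - y0) +
        eff[["unemployment"]] * unemp[, j] +
        eff[["median_income"]] * income[, j] +
        eff[["poverty"]] * poverty[, j] +
        eff[["pct_16_19"]] * p1619[, j] +
        eff[["pct_white"]] * white[, j] +
        eff[["pct_black"]] * black[, j] +
        eff[["pct_hispanic"]] * hisp[, j] +
        eff[["abortion_distance"]] * dist_at(yr - 1L) +
        noise[, j]
      e_time <- yr - (cohort_of + 1L)      # years since first treated year
      hit <- treated & !is.na(e_time) & e_time >= 0
      if (any(hit)) {
        effect_mat[hit, j] <- effect_at(config$effect_path, e_time[hit])
        idx[hit] <- idx[hit] + effect_mat[hit, j]
      }
      log1R[, j] <- idx
    }
    if (any(log1R < 0)) {
      warning("some log(1+R) values were negative and were clamped to 0")
      log1R[log1R < 0] <- 0
    }
    R <- expm1(log1R)

    births <- array(0, dim = c(C, 6, n_years))
    for (j in seq_len(n_years)) {
      mu <- pop[, , j] * R[, j] / 1000
      births[, , j] <- if (config$outcome_mode == "poisson_births") {
        matrix(stats::rpois(C * 6, mu), C, 6)
      } else mu
    }
    list(pop = pop, births = births, R = R, effect_mat = effect_mat,
         alpha = alpha, slope = slope,
         unemp = unemp, income = income, poverty = poverty, p1619 = p1619,
         white = white, black = black, hisp = hisp, dist_at = dist_at)
  })

  # assemble long panel (county fastest, year blocks)
  yr_rep <- rep(years, each = C)
  panel <- data.frame(
    county_id = rep(county_id, n_years),
    state_id = rep(state_id, n_years),
    year = yr_rep,
    stringsAsFactors = FALSE
  )
  for (a in seq_along(AGE_RANGE)) {
    panel[[birth_cols()[a]]] <- as.vector(sim$births[, a, ])
    panel[[pop_cols()[a]]] <- as.vector(sim$pop[, a, ])
  }
  # covariate matrices include the pre-year in column 1; panel years start at 2
  jj <- seq_len(n_years) + 1L
  panel$unemployment <- as.vector(sim$unemp[, jj])
  panel$median_income <- as.vector(sim$income[, jj])
  panel$poverty <- as.vector(sim$poverty[, jj])
  panel$pct_16_19 <- as.vector(sim$p1619[, jj])
  panel$pct_white <- as.vector(sim$white[, jj])
  panel$pct_black <- as.vector(sim$black[, jj])
  panel$pct_hispanic <- as.vector(sim$hisp[, jj])
  dist_full <- vapply(years, sim$dist_at, numeric(C))
  obs_knot <- yr_rep %in% config$distance_knots
  panel$abortion_distance <- ifelse(obs_knot, as.vector(dist_full), NA_real_)
  panel$funded <- as.integer(!is.na(cohort_of[panel$county_id]) &
                               yr_rep >= cohort_of[panel$county_id])
  panel <- panel[order(panel$county_id, panel$year), panel_cols()]
  rownames(panel) <- NULL

  # ground truth: effects realized on treated analysis cells (year >= g + 1)
  cell_events <- outer(cohort_of + 1L, years, function(g, yr) yr - g)
  realized <- !is.na(cell_events) & cell_events >= 0
  ev_realized <- sort(unique(cell_events[realized]))
  event_effects <- effect_at(config$effect_path, ev_realized)
  names(event_effects) <- as.character(ev_realized)
  overall_att <- mean(effect_at(config$effect_path, cell_events[realized]))
  # group-size-weighted mean of each cohort's time-averaged post effects (the
  # estimand targeted by the "overall" group-time aggregation)
  gsz <- table(cohort_of[treated])
  g_means <- vapply(names(gsz), function(g) {
    ev <- 0:(y1 - (as.integer(g) + 1L))
    mean(effect_at(config$effect_path, ev))
  }, 0)
  overall_att_group <- if (length(gsz)) {
    sum(as.integer(gsz) * g_means) / sum(gsz)
  } else 0

  truth <- structure(list(
    overall_att = overall_att,
    overall_att_group = unname(overall_att_group),
    event_effects = event_effects,
    treated_counties = cohort_of[treated],
    county_intercepts = stats::setNames(sim$alpha, county_id),
    county_trends = stats::setNames(sim$slope, county_id),
    seed = config$seed
  ), class = "sim_truth")

  structure(list(panel = panel, truth = truth, config = config),
            class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("<sim_panel> %d counties x %d years (%d rows); %d treated\n",
              length(unique(x$panel$county_id)),
              length(unique(x$panel$year)), nrow(x$panel),
              length(x$truth$treated_counties)))
  cat(sprintf("  true overall ATT (cell-weighted): %.4f\n", x$truth$overall_att))
  invisible(x)
}
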
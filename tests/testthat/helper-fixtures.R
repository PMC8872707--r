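# Fixtures and independent oracles shared across the suite.

# Small generator config whose distance knots fall inside the year range.
small_config <- function(n_states = 2, counties_per_state = 6,
                         years = c(2000, 2007),
                         cohorts = list(c(2004, 4)),
                         distance_knots = c(years[1], years[1] + 3),
                         seed = 1, ...) {
  sim_config(n_states = n_states, counties_per_state = counties_per_state,
             years = years, cohorts = cohorts,
             distance_knots = distance_knots,
             seed = seed, ...)
}

# Generate analysis rows for a small config (filters matched to its cohorts).
small_rows <- function(config, ...) {
  sp <- generate_panel(config)
  crit <- filter_criteria(main_cohort_years =
                            vapply(config$cohorts, `[`, 0L, 1))
  filt <- apply_sample_filters(sp$panel, criteria = crit)
  list(rows = build_analysis_rows(filt$records, ...), truth = sp$truth)
}

# Canonical 2x2 panel: control changes 1.0 -> 0.9, treated 1.0 -> 0.7,
# treatment switched on in period 2 => DiD of means = -0.2.
rows_2x2 <- function() {
  data.frame(county_id = rep(c("trt", "ctl"), each = 2),
             state_id = "s01",
             year = rep(1:2, 2),
             outcome = c(1.0, 0.7, 1.0, 0.9),
             treat = c(0, 1, 0, 0))
}

# Brute-force oracle: treatment coefficient from full dummy-variable OLS.
dummy_ols_treat <- function(rows, model, dropped = character()) {
  covs <- if (model >= 2) setdiff(covariate_cols(), dropped) else NULL
  fml <- paste(
    "outcome ~ treat",
    if (length(covs)) paste("+", paste(covs, collapse = " + ")) else "",
    "+ factor(county_id) + factor(paste(state_id, year))",
    if (model == 3) "+ factor(county_id):I(year - min(year))" else "")
  stats::coef(stats::lm(stats::as.formula(fml), data = rows))[["treat"]]
}

# Hand-built ten-county fixture for the sample filters: counties f01..f10,
# 3 years, with one zero-population county, two abstinence-funded, one with a
# missing covariate year, one funded off-cohort.
filter_fixture <- function() {
  ids <- sprintf("f%02d", 1:10)
  df <- expand.grid(county_id = ids, year = 2009:2011,
                    stringsAsFactors = FALSE)
  df <- df[order(df$county_id, df$year), ]
  df$state_id <- rep(c("s01", "s02"), each = 5)[match(df$county_id, ids)]
  for (cl in paste0("pop_age", 14:19)) df[[cl]] <- 100L
  for (cl in paste0("births_age", 14:19)) df[[cl]] <- 3L
  df$unemployment <- 5; df$median_income <- 50000; df$poverty <- 12
  df$pct_16_19 <- 66; df$pct_white <- 70; df$pct_black <- 10
  df$pct_hispanic <- 12; df$abortion_distance <- 40
  df$funded <- 0L
  # f01: zero teen population in 2010 (rule 1)
  df[df$county_id == "f01" & df$year == 2010, paste0("pop_age", 14:19)] <- 0L
  # f04: missing a covariate year (rule 3)
  df$unemployment[df$county_id == "f04" & df$year == 2009] <- NA
  # f05: funded from 2011, outside the main 2010/2015 cohorts (rule 4)
  df$funded[df$county_id == "f05" & df$year >= 2011] <- 1L
  # f06: funded from 2010 (main cohort; kept)
  df$funded[df$county_id == "f06" & df$year >= 2010] <- 1L
  df
}

# Hand-summed CR sandwich for a tiny design (independent oracle).
hand_sandwich <- function(X, e, cl, correction = TRUE, n_params = ncol(X)) {
  X <- as.matrix(X)
  bread <- solve(t(X) %*% X)
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in unique(cl)) {
    sg <- t(X[cl == g, , drop = FALSE]) %*% e[cl == g]
    meat <- meat + sg %*% t(sg)
  }
  G <- length(unique(cl)); N <- nrow(X)
  cf <- if (correction) G / (G - 1) * (N - 1) / (N - n_params) else 1
  cf * bread %*% meat %*% bread
}

# Minimal attgt_set for aggregation unit tests: given cell estimates, a
# cohort map and n counties, with zero influence contributions.
make_attgt <- function(cells, cohort, n) {
  counties <- names(cohort)
  gsz <- table(cohort[!is.na(cohort)])
  inf <- matrix(0, n, nrow(cells),
                dimnames = list(counties,
                                paste(cells$g, cells$t, sep = ".")))
  structure(list(cells = cells, inf = inf, counties = counties,
                 cohort = cohort, group_sizes = gsz, n = n,
                 mode = "unconditional"),
            class = "attgt_set")
}
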
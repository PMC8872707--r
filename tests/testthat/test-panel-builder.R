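test_that("rate computation and outcome transform behave as defined", {
  expect_equal(compute_rate(5, 1000), 5)
  expect_equal(compute_rate(0, 250), 0)
  expect_equal(compute_rate(3, 40), 75)
  expect_error(compute_rate(1, 0), "population")
  expect_error(compute_rate(-1, 10), "births")

  expect_equal(transform_outcome(0), 0)
  expect_equal(transform_outcome(5), log(6))
  r <- c(0, 0.3, 5, 75, 400)
  expect_equal(expm1(transform_outcome(r)), r, tolerance = 1e-12)
  expect_true(all(diff(transform_outcome(r)) > 0))
  expect_error(transform_outcome(-0.1), "non-negative")
})

test_that("sparse-covariate interpolation is exact at knots and linear beyond", {
  obs <- c(`2000` = 10, `2011` = 21)
  expect_equal(interpolate_sparse_covariate(obs, 2005), 15)
  expect_equal(interpolate_sparse_covariate(obs, 1996), 6)
  obs3 <- c(`2000` = 10, `2011` = 21, `2014` = 30)
  expect_equal(interpolate_sparse_covariate(obs3, 2017), 39)
  # exact at every knot
  expect_equal(interpolate_sparse_covariate(obs3, c(2000, 2011, 2014)),
               c(10, 21, 30))
  # collinear knots: one segment or two gives identical answers everywhere
  two_seg <- c(`2000` = 10, `2007` = 17, `2014` = 24)
  one_seg <- c(`2000` = 10, `2014` = 24)
  yrs <- 1995:2020
  expect_equal(interpolate_sparse_covariate(two_seg, yrs),
               interpolate_sparse_covariate(one_seg, yrs))
  expect_error(interpolate_sparse_covariate(c(`2000` = 1), 2005), ">= 2")
})

test_that("analysis rows lag treatment and covariates by one year", {
  cfg <- small_config(years = c(2007, 2013), cohorts = list(c(2010, 3)),
                      distance_knots = c(2007, 2010), seed = 5)
  sp <- generate_panel(cfg)
  filt <- apply_sample_filters(sp$panel,
                               criteria = filter_criteria(main_cohort_years = 2010))
  rows <- build_analysis_rows(filt$records)
  expect_false(2007 %in% rows$year)  # first year dropped (no lag available)
  trt_county <- names(sp$truth$treated_counties)[1]
  tr <- rows[rows$county_id == trt_county, ]
  expect_equal(tr$treat[tr$year == 2010], 0)
  expect_true(all(tr$treat[tr$year >= 2011] == 1))
  expect_equal(unique(tr$cohort), 2011)
  # covariates hold the previous year's value
  panel_c <- sp$panel[sp$panel$county_id == trt_county, ]
  expect_equal(tr$unemployment[tr$year == 2012],
               panel_c$unemployment[panel_c$year == 2011])

  # lag = 0 degenerate case: treated in the funding year itself
  rows0 <- build_analysis_rows(filt$records, lag = 0)
  tr0 <- rows0[rows0$county_id == trt_county, ]
  expect_equal(tr0$treat[tr0$year == 2010], 1)
  expect_true(2007 %in% rows0$year)

  # shifting funding by +1 year shifts the first treated row by +1
  shifted <- filt$records
  first <- min(shifted$year[shifted$funded == 1 &
                              shifted$county_id == trt_county])
  shifted$funded[shifted$county_id == trt_county] <-
    as.integer(shifted$year[shifted$county_id == trt_county] >= first + 1)
  rows_s <- build_analysis_rows(shifted)
  tr_s <- rows_s[rows_s$county_id == trt_county, ]
  expect_equal(min(tr_s$year[tr_s$treat == 1]),
               min(tr$year[tr$treat == 1]) + 1)
})

test_that("aggregate rate pools births over ages; age mode stacks rows", {
  df <- filter_fixture()
  df <- df[df$county_id %in% c("f02", "f03"), ]
  for (a in 14:19) df[[paste0("births_age", a)]] <- a - 13  # 1..6
  df[paste0("pop_age", 14:19)] <- 100L
  rows <- build_analysis_rows(df)
  # 21 births over 600 women -> 35 per 1,000
  expect_equal(unique(round(expm1(rows$outcome), 10)), 35)

  rows_age <- build_analysis_rows(df, age_mode = "age_specific")
  expect_equal(nrow(rows_age), nrow(rows) * 6)
  r16 <- rows_age[rows_age$age == 16, ]
  expect_equal(unique(round(expm1(r16$outcome), 10)), 30)  # 3/100 * 1000
})

test_that("unbalanced panels are rejected with the offending county named", {
  df <- filter_fixture()
  df <- df[!(df$county_id == "f07" & df$year == 2010), ]
  expect_error(build_analysis_rows(df), "f07")
})

test_that("sample filters drop counties by rule, in order, idempotently", {
  df <- filter_fixture()
  res <- apply_sample_filters(df, abstinence_counties = c("f02", "f03"))
  expect_equal(unname(res$report$excluded_counts), c(1, 2, 1, 1, 0))
  expect_equal(res$report$n_remaining, 5)
  expect_setequal(unique(res$records$county_id),
                  c("f06", "f07", "f08", "f09", "f10"))

  # no flags: everything kept
  clean <- apply_sample_filters(filter_fixture()[
    !(filter_fixture()$county_id %in% c("f01", "f04", "f05")), ])
  expect_equal(sum(clean$report$excluded_counts), 0)
  expect_equal(clean$report$n_remaining, 7)

  # a county failing rules 1 and 2 is attributed to rule 1 only
  both <- apply_sample_filters(df, abstinence_counties = c("f01", "f02", "f03"))
  expect_equal(unname(both$report$excluded_counts[1:2]), c(1, 2))
  expect_false("f01" %in% both$report$excluded_ids$abstinence_funded)

  # idempotent: filtering the filtered records excludes nothing further
  again <- apply_sample_filters(res$records,
                                abstinence_counties = c("f02", "f03"))
  expect_equal(sum(again$report$excluded_counts), 0)
  expect_equal(again$records, res$records)

  # excluded-state rule
  st <- apply_sample_filters(filter_fixture(),
                             criteria = filter_criteria(excluded_states = "s02"))
  expect_equal(unname(st$report$excluded_counts[["excluded_state"]]), 5)
})

test_that("filters fill sparse covariates by interpolation before rule 3", {
  cfg <- small_config(seed = 12)
  sp <- generate_panel(cfg)
  expect_true(anyNA(sp$panel$abortion_distance))
  res <- apply_sample_filters(sp$panel,
                              criteria = filter_criteria(main_cohort_years = 2004))
  expect_false(anyNA(res$records$abortion_distance))
  expect_equal(res$report$excluded_counts[["missing_covariate"]], 0L)
})

test_that("panel CSV round-trips through write/read", {
  cfg <- small_config(seed = 13)
  sp <- generate_panel(cfg)
  f <- tempfile(fileext = ".csv")
  write_panel_csv(sp$panel, f)
  back <- read_panel_csv(f)
  expect_equal(back$abortion_distance, sp$panel$abortion_distance)
  expect_equal(back$funded, sp$panel$funded)
  expect_equal(back$median_income, sp$panel$median_income, tolerance = 1e-9)
  unlink(f)
})
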
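# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state, so seeded package functions do
#' not perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_bad_arg <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower) {
    stop_bad_arg(sprintf("`%s` must be a single number >= %s", name, lower))
  }
  invisible(x)
}

check_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_bad_arg(sprintf("%s is missing column(s): %s", what,
                         paste(miss, collapse = ", ")))
  }
  invisible(df)
}

# Column names shared between the generator output and the panel builder.
AGE_RANGE <- 14:19
birth_cols <- function() paste0("births_age", AGE_RANGE)
pop_cols <- function() paste0("pop_age", AGE_RANGE)

#' Names of the time-varying covariates used by the covariate-adjusted models
#' @return Character vector of column names.
#' @export
covariate_cols <- function() {
  c("abortion_distance", "unemployment", "median_income", "poverty",
    "pct_16_19", "pct_white", "pct_black", "pct_hispanic")
}

panel_cols <- function() {
  c("county_id", "state_id", "year", birth_cols(), pop_cols(),
    "unemployment", "median_income", "poverty", "pct_16_19",
    "pct_white", "pct_black", "pct_hispanic", "abortion_distance", "funded")
}
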
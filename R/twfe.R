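#' Specification for a two-way fixed-effects model
#'
#' Model 1: treatment only, county and state-year fixed effects. Model 2 adds
#' the lagged time-varying covariates. Model 3 further adds county-specific
#' linear time trends.
#'
#' @param model 1, 2 or 3.
#' @param covariates covariate columns used when `model >= 2`.
#' @param cluster column defining the clustering unit for standard errors.
#' @return list of class `twfe_spec`.
#' @export
twfe_spec <- function(model = 1L, covariates = covariate_cols(),
                      cluster = "county_id") {
  model <- as.integer(model)
  if (!model %in% 1:3) stop_bad_arg("`model` must be 1, 2 or 3")
  structure(list(model_id = model,
                 include_covariates = model >= 2L,
                 include_county_trends = model == 3L,
                 covariates = covariates,
                 cluster = cluster,
                 fe_keys = c("county_id", "state_id:year")),
            class = "twfe_spec")
}

# Project columns of M onto the orthogonal complement of per-group constants
# (and, with `trend`, per-group linear-in-time terms), with weights.
proj_group <- function(M, g, w, tc = NULL, pre = NULL) {
  sw <- pre$sw
  wm <- rowsum(M * w, g)[pre$gi, , drop = FALSE] / sw
  M <- M - wm
  if (!is.null(tc)) {
    b <- rowsum(M * (w * tc), g)[pre$gi, , drop = FALSE] / pre$stt
    M <- M - b * tc
  }
  M
}

#' Two-way fixed-effects regression for the county panel
#'
#' Fits the log(1 + R) outcome on lagged treatment (and, per the model
#' specification, lagged covariates and county-specific linear trends) with
#' county and state-year fixed effects absorbed by alternating-projection
#' demeaning, and county-clustered CR1 standard errors. Point estimates agree
#' with full dummy-variable OLS to numerical tolerance.
#'
#' @param rows analysis rows from [build_analysis_rows()] (columns
#'   `county_id`, `state_id`, `year`, `outcome`, `treat`, covariates).
#' @param spec a [twfe_spec()].
#' @param weights optional non-negative observation weights (e.g. the
#'   `weight` column for population weighting), default unweighted.
#' @param demean_tol convergence tolerance of the alternating projections.
#' @param max_iter maximum projection sweeps.
#' @return Object of class `twfe_fit`: treatment estimate and percent-scale
#'   reading, full coefficient vector, cluster-robust covariance, 95% CI
#'   (t critical value with G - 1 df), counts, dropped collinear columns and
#'   within R-squared.
#' @export
fit_twfe <- function(rows, spec = twfe_spec(1L), weights = NULL,
                     demean_tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(spec, "twfe_spec"))
  need <- c("county_id", "state_id", "year", "outcome", "treat")
  if (spec$include_covariates) need <- c(need, spec$covariates)
  check_cols(rows, need, "rows")
  if (anyNA(rows[, need])) stop_bad_arg("analysis rows contain missing values")
  if (length(unique(rows$county_id)) < 2L || length(unique(rows$year)) < 2L) {
    stop_bad_arg("need at least 2 counties and 2 years")
  }
  if (stats::var(rows$treat) == 0) {
    stop_bad_arg("treatment does not vary in the sample")
  }

  xnames <- c("treat", if (spec$include_covariates) spec$covariates)
  X <- as.matrix(rows[, xnames, drop = FALSE])
  y <- rows$outcome
  n <- length(y)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0)) stop_bad_arg("bad `weights`")

  county <- factor(rows$county_id)
  sy <- factor(paste(rows$state_id, rows$year, sep = ":"))
  tc <- if (spec$include_county_trends) rows$year - min(rows$year) else NULL

  pre_c <- list(gi = as.integer(county),
                sw = rowsum(w, county)[as.integer(county), 1])
  if (!is.null(tc)) {
    tbar <- rowsum(w * tc, county)[pre_c$gi, 1] / pre_c$sw
    tc <- tc - tbar   # center time within county once; projection then exact
    pre_c$stt <- rowsum(w * tc * tc, county)[pre_c$gi, 1]
  }
  pre_s <- list(gi = as.integer(sy), sw = rowsum(w, sy)[as.integer(sy), 1])

  M <- cbind(y, X)
  scale0 <- max(abs(M), 1)
  iter <- 0L
  repeat {
    M1 <- proj_group(M, county, w, tc = tc, pre = pre_c)
    M1 <- proj_group(M1, sy, w, pre = pre_s)
    iter <- iter + 1L
    if (max(abs(M1 - M)) < demean_tol * scale0 || iter >= max_iter) {
      M <- M1
      break
    }
    M <- M1
  }
  if (iter >= max_iter) {
    warning("fixed-effect demeaning did not reach tolerance in ", max_iter,
            " sweeps")
  }
  yt <- M[, 1]
  Xt <- M[, -1, drop = FALSE]

  sw <- sqrt(w)
  Xw <- Xt * sw
  # columns absorbed by the fixed effects shrink to ~0 relative to their
  # pre-demeaning scale; detect them before QR so rank decisions are not
  # distorted by wildly different covariate scales
  nrm0 <- sqrt(colSums((X * sw)^2))
  nrm <- sqrt(colSums(Xw^2))
  nonzero <- which(nrm > 1e-8 * pmax(nrm0, 1))
  kept <- integer(0)
  if (length(nonzero)) {
    Z <- Xw[, nonzero, drop = FALSE]
    Z <- sweep(Z, 2, nrm[nonzero], "/")
    qrX <- qr(Z)
    kept <- sort(nonzero[qrX$pivot[seq_len(qrX$rank)]])
  }
  rank <- length(kept)
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), kept)]
  if ("treat" %in% dropped) {
    stop_bad_arg("treatment has no identifying variation after absorbing the ",
                 "fixed effects (no never-treated contrast within the ",
                 "state-year cells spanning treated rows)")
  }
  sc <- nrm[kept]
  Zk <- sweep(Xw[, kept, drop = FALSE], 2, sc, "/")
  fit <- stats::lm.fit(Zk, yt * sw)
  beta <- stats::setNames(fit$coefficients / sc, colnames(X)[kept])
  resid <- yt - drop(Xt[, kept, drop = FALSE] %*% beta)

  n_states <- length(unique(rows$state_id))
  k_absorbed <- nlevels(county) + nlevels(sy) - n_states +
    if (spec$include_county_trends) nlevels(county) - n_states else 0L
  K <- rank + k_absorbed
  G <- nlevels(county)
  Vz <- cluster_robust_vcov(Zk, resid * sw, rows$county_id, n_params = K)
  V <- Vz / tcrossprod(sc)
  dimnames(V) <- list(names(beta), names(beta))
  se <- sqrt(diag(V))
  tcrit <- stats::qt(0.975, df = G - 1L)
  est <- beta[["treat"]]
  ci <- est + c(-1, 1) * tcrit * se[["treat"]]
  r2w <- 1 - sum(w * resid^2) / sum(w * yt^2)

  structure(list(
    estimate = est,
    se = se[["treat"]],
    ci = ci,
    percent = interpret_as_percent(est),
    coefficients = beta,
    vcov = V,
    n_obs = n,
    n_clusters = G,
    dropped = dropped,
    r2_within = r2w,
    df_K = K,
    iterations = iter,
    spec = spec
  ), class = "twfe_fit")
}

#' Cluster-robust sandwich covariance (CR1)
#'
#' Sums scores within clusters and applies the CR1 small-sample correction
#' G/(G-1) * (N-1)/(N-K). With each observation its own cluster and the
#' correction off, this reduces to the HC0 heteroskedasticity-robust
#' covariance.
#'
#' @param design model matrix actually used in the fit (after any fixed
#'   effects were absorbed; weighted fits pass the weighted design and
#'   residuals).
#' @param residuals fitted residuals, same length as `nrow(design)`.
#' @param cluster_ids cluster membership (e.g. county id) per row.
#' @param correction apply the CR1 finite-sample factor (default `TRUE`).
#' @param n_params K in the correction; defaults to `ncol(design)`, and
#'   callers that absorbed fixed effects pass the full parameter count.
#' @return covariance matrix of the design's coefficients.
#' @export
cluster_robust_vcov <- function(design, residuals, cluster_ids,
                                correction = TRUE,
                                n_params = ncol(design)) {
  design <- as.matrix(design)
  cl <- factor(cluster_ids)
  G <- nlevels(cl)
  if (G < 2L) stop_bad_arg("need at least 2 clusters")
  N <- nrow(design)
  bread <- chol2inv(qr.R(qr(design)))
  scores <- design * residuals
  Sg <- rowsum(scores, cl)
  meat <- crossprod(Sg)
  cfac <- if (correction) G / (G - 1) * (N - 1) / (N - n_params) else 1
  cfac * bread %*% meat %*% bread
}

#' Read a log(1 + R) coefficient on the percent scale
#'
#' @param coefficient coefficient from a log(1 + R) model.
#' @return list with `exact` (100 * (exp(b) - 1)) and `rough` (100 * b, the
#'   conventional approximate reading).
#' @examples
#' interpret_as_percent(-0.033)
#' @export
interpret_as_percent <- function(coefficient) {
  list(exact = 100 * expm1(coefficient), rough = 100 * coefficient)
}

#' @export
print.twfe_fit <- function(x, ...) {
  cat(sprintf("<twfe_fit> Model %d: %d obs, %d counties\n",
              x$spec$model_id, x$n_obs, x$n_clusters))
  cat(sprintf("  treatment: %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              x$estimate, x$se, x$ci[1], x$ci[2]))
  cat(sprintf("  percent change: %.2f%% (exact), %.2f%% (rough)\n",
              x$percent$exact, x$percent$rough))
  if (length(x$dropped)) {
    cat("  dropped collinear:", paste(x$dropped, collapse = ", "), "\n")
  }
  cat(sprintf("  within R^2: %.3f\n", x$r2_within))
  invisible(x)
}
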
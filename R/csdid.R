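# Group-time ATT estimation for staggered adoption, with never-treated
# comparison counties, influence-function inference, and doubly robust
# covariate conditioning.

prep_csdid <- function(rows, covariates) {
  check_cols(rows, c("county_id", "state_id", "year", "outcome", "treat"),
             "rows")
  if ("age" %in% names(rows)) {
    stop_bad_arg("group-time ATT estimation expects one row per county-year; ",
                 "build rows with age_mode = 'aggregate'")
  }
  years <- sort(unique(rows$year))
  counties <- sort(unique(rows$county_id))
  if (nrow(rows) != length(years) * length(counties)) {
    stop_bad_arg("panel is not balanced in the outcome")
  }
  rows <- rows[order(rows$county_id, rows$year), , drop = FALSE]
  C <- length(counties); T_ <- length(years)
  Y <- matrix(rows$outcome, nrow = C, ncol = T_, byrow = TRUE,
              dimnames = list(counties, years))
  treat <- matrix(rows$treat, nrow = C, ncol = T_, byrow = TRUE)
  first <- apply(treat == 1, 1, function(v) if (any(v)) which(v)[1] else NA)
  cohort <- stats::setNames(years[first], counties)
  Xarr <- lapply(intersect(covariates, names(rows)), function(cv) {
    matrix(rows[[cv]], nrow = C, ncol = T_, byrow = TRUE,
           dimnames = list(counties, years))
  })
  names(Xarr) <- intersect(covariates, names(rows))
  list(Y = Y, years = years, counties = counties, cohort = cohort,
       Xarr = Xarr, n = C)
}

# One (g, t) cell on the treated-vs-never subsample. Returns the estimate and
# the influence-function contributions on the subsample scale.
attgt_cell <- function(DY, D, X, mode) {
  nS <- length(DY)
  if (mode == "unconditional" || is.null(X)) {
    pT <- mean(D)
    mT <- mean(DY[D == 1]); mC <- mean(DY[D == 0])
    att <- mT - mC
    psi <- D / pT * (DY - mT) - (1 - D) / (1 - pT) * (DY - mC)
    return(list(att = att, psi = psi))
  }
  # drop collinear covariate columns (intercept kept first)
  qx <- qr(X)
  X <- X[, sort(qx$pivot[seq_len(qx$rank)]), drop = FALSE]
  comp <- D == 0

  if (mode %in% c("dr", "ipw")) {
    gfit <- suppressWarnings(stats::glm.fit(X, D, family = stats::binomial()))
    p <- gfit$fitted.values
    bad <- p >= 1 - 1e-6
    if (any(bad & comp) || any(bad & !comp)) {
      stop_bad_arg("propensity overlap failure (fitted propensity ~ 1) for: ",
                   paste(utils::head(names(DY)[bad], 10), collapse = ", "))
    }
  }
  if (mode %in% c("dr", "reg")) {
    bfit <- stats::lm.fit(X[comp, , drop = FALSE], DY[comp])
    beta <- bfit$coefficients
    beta[is.na(beta)] <- 0
    m <- drop(X %*% beta)
  } else {
    m <- rep(0, nS)
  }

  wT <- D / mean(D)
  if (mode == "reg") {
    att <- mean(wT * (DY - m))
    psiT <- wT * (DY - m - att)
    MT <- colMeans(wT * X)
    A <- crossprod(X[comp, , drop = FALSE]) / nS
    IFb <- (X * (comp * (DY - m))) %*% solve(A)
    psi <- psiT - drop(IFb %*% MT)
    return(list(att = att, psi = psi))
  }

  wC0 <- (1 - D) * p / (1 - p)
  wC <- wC0 / mean(wC0)
  thT <- mean(wT * (DY - m)); thC <- mean(wC * (DY - m))
  att <- thT - thC
  psiT <- wT * (DY - m - thT)
  psiC <- wC * (DY - m - thC)
  H <- crossprod(X * sqrt(p * (1 - p))) / nS
  IFg <- (X * (D - p)) %*% solve(H)
  Mg <- colMeans(wC * X * (DY - m - thC))
  psi <- psiT - psiC - drop(IFg %*% Mg)
  if (mode == "dr") {
    MT <- colMeans(wT * X); MC <- colMeans(wC * X)
    A <- crossprod(X[comp, , drop = FALSE]) / nS
    IFb <- (X * (comp * (DY - m))) %*% solve(A)
    psi <- psi - drop(IFb %*% (MT - MC))
  }
  list(att = att, psi = psi)
}

#' Group-time average treatment effects ATT(g, t)
#'
#' Estimates the average effect at calendar time t for the cohort of counties
#' first treated in analysis year g, using never-treated counties as the
#' comparison group. Post-treatment cells (t >= g) difference the outcome
#' against the fixed base period g - 1; pre-treatment cells (t < g) are
#' year-on-year pseudo-ATTs (base t - 1) used as parallel-trend diagnostics.
#' The conditional (doubly robust) variant combines an outcome regression of
#' the never-treated outcome change on base-period covariates with inverse
#' propensity weighting from a logistic group-membership score, and its
#' influence function includes the estimation effect of both nuisance fits.
#'
#' @param rows analysis rows from [build_analysis_rows()] (aggregate mode;
#'   `treat` already carries the one-year conception lag, so g is funding
#'   year + 1).
#' @param g optional subset of groups (first treated analysis years).
#' @param t optional subset of calendar times.
#' @param mode `"unconditional"`, `"conditional"` (alias `"dr"`, doubly
#'   robust), `"reg"` (outcome regression only) or `"ipw"` (propensity
#'   weighting only).
#' @param covariates covariate columns used by the conditional variants,
#'   measured at each cell's base period.
#' @return Object of class `attgt_set`: `cells` (data.frame with g, t, event
#'   time, post indicator, estimate, SE) plus per-county influence-function
#'   contributions used by the aggregation and bootstrap routines.
#' @export
att_gt <- function(rows, g = NULL, t = NULL,
                   mode = c("unconditional", "conditional", "dr", "reg", "ipw"),
                   covariates = covariate_cols()) {
  mode <- match.arg(mode)
  if (mode == "conditional") mode <- "dr"
  pp <- prep_csdid(rows, covariates)
  never <- is.na(pp$cohort)
  if (!any(never)) {
    stop_bad_arg("no never-treated comparison counties in the panel; ",
                 "group-time ATTs are not identified")
  }
  groups <- sort(unique(pp$cohort[!is.na(pp$cohort)]))
  groups <- groups[groups - 1 >= pp$years[1]]
  if (!is.null(g)) groups <- intersect(groups, g)
  if (!length(groups)) stop_bad_arg("no estimable treated groups")

  use_x <- mode != "unconditional" && length(pp$Xarr)
  cells <- list(); psis <- list(); k <- 0L
  for (gg in groups) {
    times <- pp$years[pp$years >= pp$years[1] + 1]
    for (tt in times) {
      if (!is.null(t) && !(tt %in% t)) next
      base <- if (tt >= gg) gg - 1 else tt - 1
      if (base < pp$years[1] || base == tt) next
      inS <- (!is.na(pp$cohort) & pp$cohort == gg) | never
      DY <- pp$Y[inS, as.character(tt)] - pp$Y[inS, as.character(base)]
      D <- as.numeric(!is.na(pp$cohort[inS]))
      X <- if (use_x) {
        cbind(intercept = 1, vapply(pp$Xarr, function(M) {
          M[inS, as.character(base)]
        }, numeric(sum(inS))))
      } else NULL
      res <- attgt_cell(DY, D, X, mode)
      k <- k + 1L
      nS <- sum(inS)
      psi_full <- numeric(pp$n)
      psi_full[inS] <- res$psi * (pp$n / nS)
      cells[[k]] <- data.frame(g = gg, t = tt, event = tt - gg,
                               post = tt >= gg, att = res$att,
                               se = sqrt(sum(res$psi^2)) / nS)
      psis[[k]] <- psi_full
    }
  }
  cells <- do.call(rbind, cells)
  inf <- do.call(cbind, psis)
  rownames(inf) <- pp$counties
  colnames(inf) <- paste(cells$g, cells$t, sep = ".")
  gsz <- table(pp$cohort[!is.na(pp$cohort) & pp$cohort %in% groups])
  structure(list(cells = cells, inf = inf, counties = pp$counties,
                 cohort = pp$cohort, group_sizes = gsz, n = pp$n,
                 mode = mode),
            class = "attgt_set")
}

#' @export
print.attgt_set <- function(x, ...) {
  cat(sprintf("<attgt_set> mode=%s, %d cells, groups: %s\n", x$mode,
              nrow(x$cells), paste(names(x$group_sizes), collapse = ", ")))
  print(utils::head(x$cells, 12), row.names = FALSE)
  if (nrow(x$cells) > 12) cat("  ...\n")
  invisible(x)
}

group_weight_if <- function(x, gs, theta_g, theta, per_group_share) {
  # influence of estimating the group-share weights: shares pi_g = n_g / n
  pi_g <- as.numeric(gs) / x$n
  wif <- numeric(x$n)
  for (j in seq_along(gs)) {
    ind <- as.numeric(!is.na(x$cohort) & x$cohort == as.numeric(names(gs)[j]))
    wif <- wif + per_group_share[j] * (ind - pi_g[j])
  }
  wif
}

#' Overall ATT from a set of group-time effects
#'
#' Averages each group's post-treatment ATT(g, t) over time, then combines
#' groups with weights proportional to treated-group size (or weights every
#' post cell by its group size with `weighting = "cell"`). The SE comes from
#' the aggregated influence function, including the estimation effect of the
#' group-share weights.
#'
#' @param attgt an [att_gt()] result.
#' @param weighting `"group"` (default) or `"cell"`.
#' @return list of class `agg_overall`: `att`, `se`, `ci` (95%, normal),
#'   per-county influence function.
#' @export
aggregate_overall <- function(attgt, weighting = c("group", "cell")) {
  weighting <- match.arg(weighting)
  post <- attgt$cells$post
  if (!any(post)) stop_bad_arg("no post-treatment (g <= t) cells")
  cells <- attgt$cells[post, , drop = FALSE]
  inf <- attgt$inf[, post, drop = FALSE]
  gs <- attgt$group_sizes[names(attgt$group_sizes) %in% as.character(cells$g)]
  gvals <- as.numeric(names(gs))
  pi_g <- as.numeric(gs) / attgt$n

  theta_g <- vapply(gvals, function(gg) mean(cells$att[cells$g == gg]), 0)
  if_g <- vapply(gvals, function(gg) {
    rowMeans(inf[, cells$g == gg, drop = FALSE])
  }, numeric(attgt$n))

  if (weighting == "group") {
    w <- pi_g / sum(pi_g)
    att <- sum(w * theta_g)
    share <- (theta_g - att) / sum(pi_g)
    psi <- drop(if_g %*% w) + group_weight_if(attgt, gs, theta_g, att, share)
  } else {
    pic <- pi_g[match(cells$g, gvals)]
    D <- sum(pic)
    att <- sum(pic * cells$att) / D
    psi_cells <- drop(inf %*% (pic / D))
    share <- vapply(seq_along(gvals), function(j) {
      sel <- cells$g == gvals[j]
      (sum(cells$att[sel]) - sum(sel) * att) / D
    }, 0)
    psi <- psi_cells + group_weight_if(attgt, gs, theta_g, att, share)
  }
  se <- sqrt(sum(psi^2)) / attgt$n
  structure(list(att = att, se = se,
                 ci = att + c(-1, 1) * stats::qnorm(0.975) * se,
                 inf = psi, weighting = weighting,
                 group_means = stats::setNames(theta_g, gvals)),
            class = "agg_overall")
}

#' Event-study aggregation of group-time effects
#'
#' Re-indexes ATT(g, t) by event time e = t - g and averages across the
#' groups observing each event time, weighted by treated-group size.
#' Negative event times are the year-on-year pre-treatment diagnostics.
#'
#' @param attgt an [att_gt()] result.
#' @return Object of class `event_study`: `table` (event, estimate, se,
#'   number of contributing groups) and the per-county influence-function
#'   matrix (one column per event time) for [multiplier_bootstrap()].
#' @export
aggregate_event_study <- function(attgt) {
  cells <- attgt$cells
  events <- sort(unique(cells$event))
  n <- attgt$n
  est <- se <- numeric(length(events))
  ng <- integer(length(events))
  inf_es <- matrix(0, n, length(events),
                   dimnames = list(attgt$counties, events))
  for (j in seq_along(events)) {
    sel <- which(cells$event == events[j])
    gv <- cells$g[sel]
    gs <- attgt$group_sizes[as.character(gv)]
    w <- as.numeric(gs) / sum(gs)
    est[j] <- sum(w * cells$att[sel])
    psi <- drop(attgt$inf[, sel, drop = FALSE] %*% w)
    # weight-estimation influence (shares among groups observing this e)
    pi_g <- as.numeric(gs) / n
    share <- (cells$att[sel] - est[j]) / sum(pi_g)
    for (m in seq_along(sel)) {
      ind <- as.numeric(!is.na(attgt$cohort) & attgt$cohort == gv[m])
      psi <- psi + share[m] * (ind - pi_g[m])
    }
    inf_es[, j] <- psi
    se[j] <- sqrt(sum(psi^2)) / n
    ng[j] <- length(sel)
  }
  structure(list(table = data.frame(event = events, estimate = est, se = se,
                                    n_groups = ng),
                 inf = inf_es, n = n),
            class = "event_study")
}

#' Multiplier bootstrap over county-level influence contributions
#'
#' Perturbs the per-county influence-function contributions with Rademacher
#' weights. Pointwise scales come from the bootstrap interquartile range
#' (robust to heavy tails); the simultaneous critical value is the 95%
#' bootstrap quantile of the maximum absolute studentized deviation, giving
#' uniform confidence bands across event times.
#'
#' @param inf n-by-k matrix (or length-n vector) of influence contributions,
#'   one row per cluster (county).
#' @param reps bootstrap replications (default 999).
#' @param seed integer seed (draws are reproducible and do not disturb the
#'   caller's RNG stream).
#' @param level simultaneous confidence level (default 0.95).
#' @return list: `se` (pointwise bootstrap SEs), `crit` (simultaneous
#'   critical value, multiplies `se`), `reps`, `seed`.
#' @export
multiplier_bootstrap <- function(inf, reps = 999L, seed = 1L, level = 0.95) {
  inf <- as.matrix(inf)
  n <- nrow(inf); k <- ncol(inf)
  if (reps < 1L) stop_bad_arg("`reps` must be >= 1")
  if (n < 20L) warning("fewer than 20 clusters: bootstrap bands unreliable")
  draws <- with_seed(seed, {
    V <- matrix(sample(c(-1, 1), n * reps, replace = TRUE), n, reps)
    crossprod(inf, V) / n            # k x reps
  })
  qs <- apply(draws, 1, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
  bse <- (qs[2, ] - qs[1, ]) / (stats::qnorm(0.75) - stats::qnorm(0.25))
  stud <- abs(draws) / ifelse(bse > 0, bse, Inf)
  tmax <- apply(stud, 2, max)
  tmax[!is.finite(tmax)] <- 0
  crit <- unname(stats::quantile(tmax, level, type = 1))
  list(se = bse, crit = crit, reps = as.integer(reps), seed = as.integer(seed))
}

#' Wald test of zero pre-treatment effects
#'
#' Chi-square test of the joint null that the pre-treatment (pseudo) ATTs are
#' zero, supporting the parallel-trends assumption.
#'
#' @param pre_period_atts vector of pre-treatment estimates.
#' @param vcov their covariance matrix (e.g. from influence functions).
#' @return list: `statistic`, `df`, `p_value`.
#' @export
pretrend_wald <- function(pre_period_atts, vcov) {
  a <- as.numeric(pre_period_atts)
  if (!length(a)) stop_bad_arg("need at least one pre-period estimate")
  V <- as.matrix(vcov)
  df <- length(a)
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  kappa_big <- is.null(Vi) || !all(is.finite(Vi)) ||
    rcond(V) < .Machine$double.eps * 100
  if (kappa_big) {
    warning("singular pre-period covariance: using pseudo-inverse with ",
            "reduced degrees of freedom")
    sv <- svd(V)
    keep <- sv$d > max(sv$d) * 1e-10
    Vi <- sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
    df <- sum(keep)
  }
  stat <- drop(t(a) %*% Vi %*% a)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Full staggered-adoption analysis: ATT(g,t), aggregation, bands, pre-test
#'
#' Convenience wrapper running [att_gt()], [aggregate_overall()],
#' [aggregate_event_study()], [multiplier_bootstrap()] simultaneous bands and
#' the pre-trend Wald test ([pretrend_wald()]) on the event-study pre-period
#' estimates within `pre_window` years of adoption.
#'
#' @inheritParams att_gt
#' @param reps multiplier-bootstrap replications.
#' @param seed bootstrap seed.
#' @param weighting overall-aggregation weighting, see [aggregate_overall()].
#' @param pre_window number of pre-treatment event times entering the Wald
#'   test (counted back from adoption; `Inf` for all).
#' @return Object of class `csdid_result`: `overall` (estimate, SE, 95% CI),
#'   `event_study` (event, estimate, se, band_lo, band_hi), `pretrend`
#'   (statistic, df, p), bootstrap settings.
#' @export
fit_csdid <- function(rows,
                      mode = c("unconditional", "conditional", "dr", "reg",
                               "ipw"),
                      covariates = covariate_cols(), reps = 999L, seed = 1L,
                      weighting = c("group", "cell"), pre_window = 5) {
  mode <- match.arg(mode)
  attgt <- att_gt(rows, mode = mode, covariates = covariates)
  overall <- aggregate_overall(attgt, weighting = match.arg(weighting))
  es <- aggregate_event_study(attgt)
  boot <- multiplier_bootstrap(es$inf, reps = reps, seed = seed)
  tab <- es$table
  tab$band_lo <- tab$estimate - boot$crit * boot$se
  tab$band_hi <- tab$estimate + boot$crit * boot$se

  pre_idx <- which(tab$event < 0 & tab$event >= -pre_window)
  pretrend <- if (length(pre_idx)) {
    Vp <- crossprod(es$inf[, pre_idx, drop = FALSE]) / es$n^2
    pretrend_wald(tab$estimate[pre_idx], Vp)
  } else NULL

  structure(list(overall = overall, event_study = tab, pretrend = pretrend,
                 attgt = attgt, boot = boot, mode = mode,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "csdid_result")
}

#' @export
print.csdid_result <- function(x, ...) {
  cat(sprintf("<csdid_result> mode=%s\n", x$mode))
  cat(sprintf("  overall ATT: %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              x$overall$att, x$overall$se, x$overall$ci[1], x$overall$ci[2]))
  pc <- interpret_as_percent(x$overall$att)
  cat(sprintf("  percent change: %.2f%% (exact)\n", pc$exact))
  if (!is.null(x$pretrend)) {
    cat(sprintf("  pre-trend Wald: chi2(%d) = %.2f, p = %.3f\n",
                x$pretrend$df, x$pretrend$statistic, x$pretrend$p_value))
  }
  cat(sprintf("  event study: %d event times (bands at 95%%, %d bootstrap reps)\n",
              nrow(x$event_study), x$reps))
  invisible(x)
}
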
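#' Panel regressions with year-specific temperature-anomaly slopes
#'
#' The estimators in this file are ordinary least squares on dummy
#' expansions of the two-way fixed-effects model: region intercepts,
#' year intercepts, and either a single anomaly slope
#' ([fit_fe_constant()]) or one slope per study year ([fit_tvc()]).
#' Year-specific slopes are obtained by interacting the anomaly with
#' year indicators, which on a balanced design reproduces independent
#' per-year within-regressions exactly. Inference defaults to
#' cluster-robust (by region) covariance via \pkg{sandwich}.
#'
#' @name regressions
NULL

.prep_panel <- function(panel, outcome, covariates, extra = "anomaly",
                        min_per_region = 2L) {
  need <- c("region_id", "year", outcome, extra, covariates)
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0L) stop("panel missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(paste(panel$region_id, panel$year))) {
    stop("duplicated (region, year) keys in panel")
  }
  df <- panel[, need]
  names(df)[names(df) == outcome] <- ".y"
  cc <- stats::complete.cases(df)
  if (any(!cc)) {
    message(sum(!cc), " incomplete panel row(s) dropped (listwise deletion)")
    df <- df[cc, ]
  }
  df$region_f <- factor(df$region_id)
  df$year_f <- factor(df$year)
  tab <- table(df$region_f)
  if (any(tab < min_per_region)) {
    stop("region(s) with fewer than ", min_per_region, " observations: ",
         paste(names(tab)[tab < min_per_region], collapse = ", "))
  }
  df
}

.panel_vcov <- function(fit, df, vcov_type) {
  # cluster: HC0 meat with the G/(G-1) cluster adjustment only; a
  # residual-df correction counting the absorbed region/year dummies
  # would overstate the variance in dummy-saturated panels
  switch(vcov_type,
         cluster = sandwich::vcovCL(fit, cluster = df$region_f,
                                    type = "HC0", cadjust = TRUE),
         hc = sandwich::vcovHC(fit, type = "HC1"),
         classical = stats::vcov(fit))
}

.crit_df <- function(fit, df, vcov_type) {
  if (vcov_type == "cluster") nlevels(df$region_f) - 1L else fit$df.residual
}

.check_full_rank <- function(fit) {
  bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(bad) > 0L) {
    stop("rank-deficient design; collinear column(s): ", paste(bad, collapse = ", "))
  }
}

.coef_table <- function(est, se, crit_df, conf_level) {
  est <- unname(est)
  se <- rep(unname(se), length.out = length(est))
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = crit_df)
  data.frame(estimate = est, se = se,
             ci_low = est - tq * se, ci_high = est + tq * se,
             p = 2 * stats::pt(-abs(est / se), df = crit_df))
}

#' Constant-coefficient two-way fixed-effects regression
#'
#' Estimates a single anomaly slope (and control slopes) with region
#' and year fixed effects; equivalent to the within estimator.
#'
#' @param panel region-year data frame (see [simulate_panel()] for the
#'   expected columns).
#' @param outcome name of the outcome column (`"msfi"` or `"sfi"`;
#'   percent scale).
#' @param covariates control columns entering with constant
#'   coefficients.
#' @param vcov_type `"cluster"` (by region, the default), `"hc"`
#'   (heteroskedasticity-robust HC1) or `"classical"`.
#' @param conf_level confidence level for reported intervals.
#' @return object of class `c("fe_fit", "panel_fit")`: list with
#'   `beta` (coefficient table for anomaly + controls), `alpha_hat`,
#'   `year_effects`, `vcov`, `model`, `n_obs`, `dof`.
#' @export
fit_fe_constant <- function(panel, outcome = c("msfi", "sfi"),
                            covariates = c("shdi_scaled", "drought"),
                            vcov_type = c("cluster", "hc", "classical"),
                            conf_level = 0.95) {
  outcome <- match.arg(outcome)
  vcov_type <- match.arg(vcov_type)
  df <- .prep_panel(panel, outcome, covariates)
  rhs <- paste(c("0", "region_f", "year_f", "anomaly", covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df)
  .check_full_rank(fit)
  V <- .panel_vcov(fit, df, vcov_type)
  cdf <- .crit_df(fit, df, vcov_type)
  terms <- c("anomaly", covariates)
  tab <- .coef_table(stats::coef(fit)[terms], sqrt(diag(V)[terms]), cdf, conf_level)
  tab <- cbind(term = terms, tab)
  rownames(tab) <- NULL
  a_idx <- grep("^region_f", names(stats::coef(fit)))
  structure(list(beta = tab, alpha_hat = stats::coef(fit)[a_idx],
                 year_effects = stats::coef(fit)[grep("^year_f\\d+$", names(stats::coef(fit)))],
                 vcov = V, vcov_type = vcov_type, model = fit, data = df,
                 outcome = outcome, covariates = covariates,
                 n_obs = nrow(df), dof = fit$df.residual, crit_df = cdf,
                 conf_level = conf_level),
            class = c("fe_fit", "panel_fit"))
}

#' Time-varying-coefficient fixed-effects regression
#'
#' Estimates one anomaly slope per study year (anomaly interacted with
#' year indicators) alongside constant-coefficient controls, region
#' fixed effects and, by default, year intercepts. Control slopes can
#' optionally vary by year as well.
#'
#' @inheritParams fit_fe_constant
#' @param year_intercepts include year fixed effects (default TRUE;
#'   they remain identified because the anomaly varies across regions
#'   within each year — a year with degenerate anomaly triggers an
#'   explicit error).
#' @param time_varying_controls if TRUE the control slopes also get
#'   year interactions.
#' @param region_fe include region fixed effects (default TRUE; set
#'   FALSE for pooled cross-sections, in which case the year-specific
#'   slopes equal independent per-year regressions on a balanced
#'   panel).
#' @param time_varying if FALSE the anomaly slope is constrained equal
#'   across years, reproducing [fit_fe_constant()] exactly (the lambda
#'   table then repeats the single slope for every year).
#' @return object of class `c("tvc_fit", "panel_fit")` with `lambda`
#'   (per-year coefficient table: `year`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p`), `gamma` (controls), `alpha_hat`, `year_effects`,
#'   `vcov` (full), `lambda_vcov`, `model`, `n_obs`, `dof`.
#' @export
fit_tvc <- function(panel, outcome = c("msfi", "sfi"),
                    covariates = c("shdi_scaled", "drought"),
                    year_intercepts = TRUE, time_varying_controls = FALSE,
                    region_fe = TRUE, time_varying = TRUE,
                    vcov_type = c("cluster", "hc", "classical"),
                    conf_level = 0.95) {
  outcome <- match.arg(outcome)
  vcov_type <- match.arg(vcov_type)
  df <- .prep_panel(panel, outcome, covariates)

  yr_tab <- table(df$year_f)
  if (any(yr_tab < 2L)) {
    stop("every study year must be present in at least 2 regions; offending year(s): ",
         paste(names(yr_tab)[yr_tab < 2L], collapse = ", "))
  }
  if (time_varying) {
    v_by_year <- tapply(df$anomaly, df$year_f, stats::var)
    if (any(v_by_year <= .Machine$double.eps)) {
      stop("anomaly has zero cross-sectional variance in year(s): ",
           paste(names(v_by_year)[v_by_year <= .Machine$double.eps], collapse = ", "),
           "; the year-specific slope is not identified there")
    }
  }

  ctrl <- if (time_varying_controls) paste0("year_f:", covariates) else covariates
  anom_term <- if (time_varying) "year_f:anomaly" else "anomaly"
  rhs <- c("0", if (region_fe) "region_f", if (year_intercepts) "year_f",
           anom_term, ctrl)
  fml <- if (region_fe || year_intercepts) {
    paste(".y ~", paste(rhs, collapse = " + "))
  } else {
    paste(".y ~", paste(rhs[-1L], collapse = " + "))
  }
  fit <- stats::lm(stats::as.formula(fml), data = df)
  .check_full_rank(fit)
  V <- .panel_vcov(fit, df, vcov_type)
  cdf <- .crit_df(fit, df, vcov_type)

  years <- sort(unique(df$year))
  if (time_varying) {
    lam_names <- paste0("year_f", years, ":anomaly")
    stopifnot(all(lam_names %in% names(stats::coef(fit))))
    lam <- .coef_table(stats::coef(fit)[lam_names], sqrt(diag(V)[lam_names]),
                       cdf, conf_level)
  } else {
    lam_names <- rep("anomaly", length(years))
    lam <- .coef_table(stats::coef(fit)[lam_names], sqrt(diag(V)["anomaly"]),
                       cdf, conf_level)
  }
  lam <- cbind(year = years, lam)
  rownames(lam) <- NULL

  gam_names <- if (time_varying_controls) {
    unlist(lapply(covariates, function(cv) paste0("year_f", years, ":", cv)))
  } else covariates
  gam <- .coef_table(stats::coef(fit)[gam_names], sqrt(diag(V)[gam_names]),
                     cdf, conf_level)
  gam <- cbind(term = gam_names, gam)
  rownames(gam) <- NULL

  a_idx <- grep("^region_f", names(stats::coef(fit)))
  structure(list(lambda = lam, gamma = gam,
                 alpha_hat = stats::coef(fit)[a_idx],
                 year_effects = stats::coef(fit)[grep("^year_f\\d+$", names(stats::coef(fit)))],
                 vcov = V, lambda_vcov = V[lam_names, lam_names],
                 vcov_type = vcov_type, model = fit, data = df,
                 outcome = outcome, covariates = covariates,
                 years = years, n_obs = nrow(df), dof = fit$df.residual,
                 crit_df = cdf, conf_level = conf_level,
                 time_varying = time_varying,
                 time_varying_controls = time_varying_controls),
            class = c("tvc_fit", "panel_fit"))
}

#' @export
print.panel_fit <- function(x, ...) {
  cat("Two-way fixed-effects panel fit (outcome: ", x$outcome,
      ", vcov: ", x$vcov_type, ", n = ", x$n_obs, ")\n\n", sep = "")
  if (!is.null(x$lambda)) {
    cat("Year-specific anomaly coefficients (pp per degC):\n")
    print(x$lambda, digits = 4)
    cat("\nControls:\n")
    print(x$gamma, digits = 4)
  } else {
    print(x$beta, digits = 4)
  }
  invisible(x)
}

.binned_design <- function(panel, outcome, covariates, reference = "bin_02_04",
                           region_fe = TRUE) {
  labs <- anomaly_bin_labels()
  bins <- setdiff(labs, reference)
  df <- .prep_panel(panel, outcome, covariates, extra = bins,
                    min_per_region = if (region_fe) 2L else 1L)
  degenerate <- vapply(bins, function(b) stats::var(df[[b]]) <= .Machine$double.eps,
                       logical(1))
  if (all(degenerate)) {
    stop("all months fall in the reference bin (", reference,
         ") for every region-year; bin coefficients are not identified")
  }
  if (any(degenerate)) {
    stop("bin column(s) with no variation: ", paste(bins[degenerate], collapse = ", "))
  }
  list(df = df, bins = bins)
}

#' Binned-anomaly regression with year-specific bin coefficients
#'
#' Covariates are the month counts in the four non-reference monthly
#' anomaly bins (reference bin: 0.2-0.4 degC), each interacted with
#' year; SHDI and drought enter with constant coefficients; region
#' fixed effects included.
#'
#' @inheritParams fit_fe_constant
#' @return object of class `c("binned_fit", "panel_fit")` with
#'   `coefficients` (tidy table: `term`, `bin`, `year`, `estimate`,
#'   `se`, `ci_low`, `ci_high`, `p`), `gamma`, `vcov`, `model`.
#' @export
fit_binned_tvc <- function(panel, outcome = c("msfi", "sfi"),
                           covariates = c("shdi_scaled", "drought"),
                           region_fe = TRUE,
                           vcov_type = c("cluster", "hc", "classical"),
                           conf_level = 0.95) {
  outcome <- match.arg(outcome)
  vcov_type <- match.arg(vcov_type)
  d <- .binned_design(panel, outcome, covariates, region_fe = region_fe)
  df <- d$df
  one_year <- nlevels(df$year_f) < 2L
  bin_terms <- if (one_year) d$bins else paste0("year_f:", d$bins)
  rhs <- c(if (region_fe) c("0", "region_f") else "1", bin_terms, covariates)
  fit <- stats::lm(stats::as.formula(paste(".y ~", paste(rhs, collapse = " + "))),
                   data = df)
  .check_full_rank(fit)
  V <- .panel_vcov(fit, df, vcov_type)
  cdf <- .crit_df(fit, df, vcov_type)
  years <- sort(unique(df$year))
  grid <- expand.grid(year = years, bin = d$bins, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  nm <- if (one_year) grid$bin else paste0("year_f", grid$year, ":", grid$bin)
  stopifnot(all(nm %in% names(stats::coef(fit))))
  tab <- .coef_table(stats::coef(fit)[nm], sqrt(diag(V)[nm]), cdf, conf_level)
  tab <- cbind(term = nm, grid[, c("bin", "year")], tab)
  rownames(tab) <- NULL
  gam <- .coef_table(stats::coef(fit)[covariates], sqrt(diag(V)[covariates]),
                     cdf, conf_level)
  gam <- cbind(term = covariates, gam)
  structure(list(coefficients = tab, gamma = gam, vcov = V, model = fit,
                 data = df, outcome = outcome, bins = d$bins, years = years,
                 vcov_type = vcov_type, n_obs = nrow(df), crit_df = cdf,
                 conf_level = conf_level),
            class = c("binned_fit", "panel_fit"))
}

#' Binned-anomaly regression with constant bin coefficients
#'
#' As [fit_binned_tvc()] but with a single coefficient per bin (no year
#' interactions); with a single study year the two coincide.
#'
#' @inheritParams fit_fe_constant
#' @export
fit_binned_constant <- function(panel, outcome = c("msfi", "sfi"),
                                covariates = c("shdi_scaled", "drought"),
                                region_fe = TRUE,
                                vcov_type = c("cluster", "hc", "classical"),
                                conf_level = 0.95) {
  outcome <- match.arg(outcome)
  vcov_type <- match.arg(vcov_type)
  d <- .binned_design(panel, outcome, covariates, region_fe = region_fe)
  df <- d$df
  rhs <- c(if (region_fe) c("0", "region_f") else "1", d$bins, covariates)
  fit <- stats::lm(stats::as.formula(paste(".y ~", paste(rhs, collapse = " + "))),
                   data = df)
  .check_full_rank(fit)
  V <- .panel_vcov(fit, df, vcov_type)
  cdf <- .crit_df(fit, df, vcov_type)
  nm <- d$bins
  tab <- .coef_table(stats::coef(fit)[nm], sqrt(diag(V)[nm]), cdf, conf_level)
  tab <- cbind(term = nm, bin = nm, year = NA_integer_, tab)
  rownames(tab) <- NULL
  gam <- .coef_table(stats::coef(fit)[covariates], sqrt(diag(V)[covariates]),
                     cdf, conf_level)
  gam <- cbind(term = covariates, gam)
  structure(list(coefficients = tab, gamma = gam, vcov = V, model = fit,
                 data = df, outcome = outcome, bins = d$bins,
                 vcov_type = vcov_type, n_obs = nrow(df), crit_df = cdf,
                 conf_level = conf_level),
            class = c("binned_fit", "panel_fit"))
}

#' Tidy coefficient table from a panel fit
#'
#' @param fit a fit from [fit_tvc()], [fit_fe_constant()],
#'   [fit_binned_tvc()] or [fit_binned_constant()].
#' @return data frame with columns `term`, `year` (NA for constant
#'   terms), `estimate`, `se`, `ci_low`, `ci_high`, `p`.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "panel_fit"))
  if (inherits(fit, "tvc_fit")) {
    lam <- cbind(term = "anomaly", fit$lambda)
    gam <- cbind(fit$gamma[, "term", drop = FALSE], year = NA_integer_,
                 fit$gamma[, setdiff(names(fit$gamma), "term")])
    out <- rbind(lam[, c("term", "year", "estimate", "se", "ci_low", "ci_high", "p")],
                 gam[, c("term", "year", "estimate", "se", "ci_low", "ci_high", "p")])
  } else if (inherits(fit, "binned_fit")) {
    tab <- fit$coefficients
    tab$term <- tab$bin
    gam <- cbind(fit$gamma[, "term", drop = FALSE], year = NA_integer_,
                 fit$gamma[, setdiff(names(fit$gamma), "term")])
    out <- rbind(tab[, c("term", "year", "estimate", "se", "ci_low", "ci_high", "p")],
                 gam[, c("term", "year", "estimate", "se", "ci_low", "ci_high", "p")])
  } else {
    out <- cbind(fit$beta[, "term", drop = FALSE], year = NA_integer_,
                 fit$beta[, setdiff(names(fit$beta), "term")])
    out <- out[, c("term", "year", "estimate", "se", "ci_low", "ci_high", "p")]
  }
  rownames(out) <- NULL
  out
}
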
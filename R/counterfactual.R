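#' Factual versus trend-extrapolated counterfactual anomalies
#'
#' The counterfactual scenario extends each region's historical
#' (baseline-window) warming trajectory: a linear trend is fit to the
#' region's annual mean temperatures over the baseline, extrapolated
#' through the study years, and converted to an anomaly against the
#' baseline mean. The factual anomaly is the observed one from
#' [annual_temperature_anomaly()]. An externally supplied counterfactual
#' (e.g. pre-aggregated natural-forcing model output) can override the
#' trend extrapolation.
#'
#' @param series monthly climate data frame (must cover the baseline).
#' @param baseline `c(first_year, last_year)` baseline window.
#' @param study_years years to build scenarios for.
#' @param override optional data frame `region_id`, `year`,
#'   `anomaly_counterfactual` replacing the trend extrapolation.
#' @return data frame `region_id`, `year`, `anomaly_factual`,
#'   `anomaly_counterfactual`.
#' @export
counterfactual_anomaly <- function(series, baseline = c(1981L, 2010L),
                                   study_years = 2014:2019, override = NULL) {
  anom <- annual_temperature_anomaly(series, baseline)
  fact <- anom[anom$year %in% study_years, c("region_id", "year", "anomaly")]
  names(fact)[3] <- "anomaly_factual"

  bl <- series[series$year >= baseline[1] & series$year <= baseline[2], ]
  key <- interaction(bl$region_id, bl$year, drop = TRUE)
  ann <- data.frame(region_id = tapply(as.character(bl$region_id), key, `[`, 1L),
                    year = as.integer(tapply(bl$year, key, `[`, 1L)),
                    mean_t = as.numeric(tapply(bl$tmean_c, key, mean)))
  cf <- do.call(rbind, lapply(split(ann, ann$region_id), function(a) {
    tr <- stats::lm(mean_t ~ year, data = a)
    bl_mean <- mean(a$mean_t)
    data.frame(region_id = a$region_id[1L], year = study_years,
               anomaly_counterfactual =
                 as.numeric(stats::predict(tr, data.frame(year = study_years))) - bl_mean)
  }))
  if (!is.null(override)) {
    if (!all(c("region_id", "year", "anomaly_counterfactual") %in% names(override))) {
      stop("override must have columns region_id, year, anomaly_counterfactual")
    }
    cf <- override[, c("region_id", "year", "anomaly_counterfactual")]
  }
  out <- merge(fact, cf, by = c("region_id", "year"))
  if (nrow(out) != nrow(fact)) {
    stop("counterfactual scenario does not cover the same (region, year) keys")
  }
  out <- out[order(out$region_id, out$year), ]
  rownames(out) <- NULL
  out
}

#' Predicted prevalence under a given anomaly scenario
#'
#' Evaluates the fitted linear model at the panel's covariates with the
#' anomaly column replaced by the scenario anomaly: predicted = region
#' effect + year effect + lambda_t * anomaly + controls. Predictions
#' are clipped to [0, 100]; the number of clipped values is reported in
#' `attr(, "n_clipped")`. Because the model is linear, the difference
#' between two scenarios is exactly lambda_t * (difference in
#' anomalies) per region-year wherever no clipping occurs.
#'
#' @param fit a [fit_tvc()] (or [fit_fe_constant()]) object.
#' @param panel region-year data frame with the fit's covariate
#'   columns.
#' @param anomaly scenario anomaly: either a numeric vector aligned
#'   with `panel` rows or the name of a column in `panel`.
#' @return data frame `region_id`, `year`, `predicted`.
#' @export
predict_prevalence <- function(fit, panel, anomaly = "anomaly") {
  stopifnot(inherits(fit, "panel_fit"))
  if (is.character(anomaly) && length(anomaly) == 1L) {
    if (!anomaly %in% names(panel)) stop("column not found in panel: ", anomaly)
    anomaly <- panel[[anomaly]]
  }
  if (length(anomaly) != nrow(panel)) stop("scenario anomaly length does not match panel")
  fitted_regions <- levels(fit$data$region_f)
  new_regions <- setdiff(unique(as.character(panel$region_id)), fitted_regions)
  if (length(new_regions) > 0L) {
    stop("region(s) absent from the fit (no fixed effect available): ",
         paste(new_regions, collapse = ", "))
  }
  nd <- panel
  nd$anomaly <- anomaly
  nd$region_f <- factor(as.character(panel$region_id), levels = fitted_regions)
  nd$year_f <- factor(panel$year, levels = levels(fit$data$year_f))
  if (anyNA(nd$year_f)) stop("panel contains years absent from the fit")
  pred <- as.numeric(stats::predict(fit$model, newdata = nd))
  n_clipped <- sum(pred < 0 | pred > 100, na.rm = TRUE)
  if (n_clipped > 0L) message(n_clipped, " prediction(s) clipped to [0, 100]")
  out <- data.frame(region_id = as.character(panel$region_id), year = panel$year,
                    predicted = pmin(pmax(pred, 0), 100))
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Difference columns for an attribution table
#'
#' Given group-level factual and counterfactual prevalences for both
#' outcomes, appends the attributable differences (factual minus
#' counterfactual, percentage points; positive values mean observed
#' warming worsened food insecurity).
#'
#' @param tab data frame with columns `group`, `msfi_factual`,
#'   `msfi_counterfactual`, `sfi_factual`, `sfi_counterfactual`
#'   (percent).
#' @return the table with `msfi_difference` and `sfi_difference`
#'   appended, class `attribution_result`.
#' @export
attribution_table <- function(tab) {
  need <- c("group", "msfi_factual", "msfi_counterfactual",
            "sfi_factual", "sfi_counterfactual")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) stop("attribution table missing column(s): ",
                              paste(miss, collapse = ", "))
  tab$msfi_difference <- tab$msfi_factual - tab$msfi_counterfactual
  tab$sfi_difference <- tab$sfi_factual - tab$sfi_counterfactual
  class(tab) <- c("attribution_result", class(tab))
  tab
}

#' Attribute food-insecurity prevalence to observed warming
#'
#' Predicts both outcomes under the factual and counterfactual anomaly
#' scenarios, averages predictions within region groups (weighted mean
#' over member region-years), and reports the group-level differences
#' in percentage points. A delta-method confidence interval on each
#' difference is derived from the covariance of the year-specific
#' anomaly coefficients: the group difference is a fixed linear
#' combination c'lambda with c_t the weighted mean anomaly gap in year
#' t, so its variance is c' V c.
#'
#' @param fit_msfi,fit_sfi [fit_tvc()] objects for the two outcomes.
#' @param panel region-year covariate data frame.
#' @param scenarios data frame from [counterfactual_anomaly()]
#'   (`region_id`, `year`, `anomaly_factual`, `anomaly_counterfactual`).
#' @param group_map data frame `region_id`, `group`; every panel region
#'   must map to exactly one group.
#' @param group_weights optional data frame `region_id`, `weight`
#'   (>= 0); equal weights by default.
#' @return [attribution_table()] with delta-method CI columns
#'   (`msfi_diff_ci_low/high`, `sfi_diff_ci_low/high`).
#' @export
attribute <- function(fit_msfi, fit_sfi, panel, scenarios, group_map,
                      group_weights = NULL) {
  if (!all(c("region_id", "group") %in% names(group_map))) {
    stop("group_map must have columns region_id, group")
  }
  if (anyDuplicated(group_map$region_id)) {
    stop("each region must map to exactly one group")
  }
  p <- merge(panel, scenarios, by = c("region_id", "year"))
  if (nrow(p) != nrow(panel)) stop("scenarios do not cover all panel (region, year) keys")
  p <- merge(p, group_map, by = "region_id")
  if (nrow(p) != nrow(panel)) {
    stop("unmapped region(s): ",
         paste(setdiff(panel$region_id, group_map$region_id), collapse = ", "))
  }
  if (is.null(group_weights)) {
    p$w <- 1
  } else {
    if (!all(c("region_id", "weight") %in% names(group_weights))) {
      stop("group_weights must have columns region_id, weight")
    }
    if (any(group_weights$weight < 0)) stop("group weights must be non-negative")
    p$w <- group_weights$weight[match(p$region_id, group_weights$region_id)]
    if (anyNA(p$w)) stop("group_weights missing for some regions")
  }
  p <- p[order(p$region_id, p$year), ]

  preds <- list(
    msfi_factual = predict_prevalence(fit_msfi, p, p$anomaly_factual)$predicted,
    msfi_counterfactual = predict_prevalence(fit_msfi, p, p$anomaly_counterfactual)$predicted,
    sfi_factual = predict_prevalence(fit_sfi, p, p$anomaly_factual)$predicted,
    sfi_counterfactual = predict_prevalence(fit_sfi, p, p$anomaly_counterfactual)$predicted
  )

  groups <- sort(unique(as.character(p$group)))
  rows <- lapply(groups, function(g) {
    i <- p$group == g
    if (!any(i)) stop("empty group: ", g)
    w <- p$w[i]
    if (sum(w) <= 0) stop("group ", g, " has zero total weight")
    wm <- function(v) sum(w * v[i]) / sum(w)
    # delta-method se of the difference: c_t = weighted mean anomaly gap in year t
    gap <- p$anomaly_factual - p$anomaly_counterfactual
    se_for <- function(fit) {
      cvec <- vapply(fit$years, function(yy) {
        j <- i & p$year == yy
        sum(p$w[j] * gap[j]) / sum(w)
      }, numeric(1))
      sqrt(as.numeric(t(cvec) %*% fit$lambda_vcov %*% cvec))
    }
    se_m <- se_for(fit_msfi)
    se_s <- se_for(fit_sfi)
    data.frame(group = g,
               msfi_factual = wm(preds$msfi_factual),
               msfi_counterfactual = wm(preds$msfi_counterfactual),
               sfi_factual = wm(preds$sfi_factual),
               sfi_counterfactual = wm(preds$sfi_counterfactual),
               msfi_diff_se = se_m, sfi_diff_se = se_s)
  })
  out <- do.call(rbind, rows)
  out <- attribution_table(out)
  z <- stats::qnorm(0.975)
  out$msfi_diff_ci_low <- out$msfi_difference - z * out$msfi_diff_se
  out$msfi_diff_ci_high <- out$msfi_difference + z * out$msfi_diff_se
  out$sfi_diff_ci_low <- out$sfi_difference - z * out$sfi_diff_se
  out$sfi_diff_ci_high <- out$sfi_difference + z * out$sfi_diff_se
  rownames(out) <- NULL
  out
}

#' Published regional counterfactual prevalences (reference values)
#'
#' Group-level factual and counterfactual prevalences of
#' moderate-to-severe and severe food insecurity over 2014-2019, as
#' published for the four-region aggregation of the 83-country sample.
#' Used for arithmetic cross-checks of the attribution table.
#'
#' @return data frame with columns `group`, `msfi_factual`,
#'   `msfi_counterfactual`, `sfi_factual`, `sfi_counterfactual`
#'   (percent).
#' @export
reference_attribution_inputs <- function() {
  data.frame(
    group = c("Africa", "Americas", "Asia", "Europe"),
    msfi_factual = c(49.89, 32.72, 33.49, 13.19),
    msfi_counterfactual = c(47.65, 30.72, 31.35, 11.73),
    sfi_factual = c(22.68, 10.67, 9.69, 2.05),
    sfi_counterfactual = c(21.80, 10.11, 9.10, 1.86)
  )
}
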
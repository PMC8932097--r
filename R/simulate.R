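#' Parameters for the synthetic climate generator
#'
#' Defaults emulate the study sample: 83 regions observed monthly over
#' 1981-2019, anomalies measured against the 1981-2010 baseline, a
#' historical per-region warming trend, and excess warming of 0.03
#' degC/yr beyond the historical trend after the baseline ends (the
#' anthropogenic acceleration that the counterfactual analysis
#' removes). The default historical trends are drawn uniformly with
#' mean (0.56 - 6.5 * 0.03)/21 degC/yr so that the expected mean
#' anomaly over 2014-2019 is 0.56 degC, of which about 0.2 degC is the
#' excess over the historical trajectory.
#'
#' @param n_regions number of regions.
#' @param start_year,end_year span of the monthly series (must cover the
#'   baseline and the study window).
#' @param baseline_start,baseline_end climatological baseline years.
#' @param warming_trend historical trend, degC per year; scalar,
#'   length-`n_regions` vector, or `NULL` for the default draw.
#' @param post_baseline_extra_trend additional warming (degC per year,
#'   scalar or per region) applied from the first post-baseline year
#'   onward; 0 makes the factual trajectory follow the historical trend
#'   exactly.
#' @param seasonal_amplitude degC amplitude of the seasonal cycle.
#' @param temp_noise_sd degC sd of monthly temperature noise.
#' @param precip_gamma_shape,precip_gamma_scale monthly precipitation
#'   gamma parameters (scalar or length 12), mm.
#' @param zero_precip_prob point mass at zero precipitation.
#' @param seed integer seed.
#' @return validated parameter list of class `climate_gen_params`.
#' @export
climate_gen_params <- function(n_regions = 83L,
                               start_year = 1981L, end_year = 2019L,
                               baseline_start = 1981L, baseline_end = 2010L,
                               warming_trend = NULL,
                               post_baseline_extra_trend = 0.03,
                               seasonal_amplitude = 8,
                               temp_noise_sd = 0.2,
                               precip_gamma_shape = 2,
                               precip_gamma_scale = 50,
                               zero_precip_prob = 0.05,
                               seed = 1L) {
  p <- list(n_regions = as.integer(n_regions), start_year = as.integer(start_year),
            end_year = as.integer(end_year), baseline_start = as.integer(baseline_start),
            baseline_end = as.integer(baseline_end), warming_trend = warming_trend,
            post_baseline_extra_trend = post_baseline_extra_trend,
            seasonal_amplitude = seasonal_amplitude, temp_noise_sd = temp_noise_sd,
            precip_gamma_shape = precip_gamma_shape,
            precip_gamma_scale = precip_gamma_scale,
            zero_precip_prob = zero_precip_prob, seed = as.integer(seed))
  if (p$n_regions < 1L) stop("n_regions must be positive")
  if (p$start_year > p$baseline_start) stop("start_year must not exceed baseline_start")
  if (p$baseline_end <= p$baseline_start) stop("baseline window is empty")
  if (p$temp_noise_sd < 0) stop("temp_noise_sd must be non-negative")
  if (any(p$precip_gamma_shape <= 0) || any(p$precip_gamma_scale <= 0)) {
    stop("precipitation gamma parameters must be positive")
  }
  if (p$zero_precip_prob < 0 || p$zero_precip_prob > 1) {
    stop("zero_precip_prob must be in [0, 1]")
  }
  if (!is.null(warming_trend) &&
      !(length(warming_trend) %in% c(1L, p$n_regions))) {
    stop("warming_trend must be scalar, length n_regions, or NULL")
  }
  if (!length(p$post_baseline_extra_trend) %in% c(1L, p$n_regions)) {
    stop("post_baseline_extra_trend must be scalar or length n_regions")
  }
  class(p) <- "climate_gen_params"
  p
}

#' Simulate per-region monthly climate series
#'
#' Temperature = region mean + seasonal sinusoid + historical trend
#' times (year - baseline midpoint) + excess trend times the years
#' elapsed since the baseline ended + Gaussian noise. Precipitation is
#' drawn from a month-specific gamma with an explicit point mass at
#' zero. Because the historical trend is centred on the baseline
#' midpoint and the excess term is zero inside the baseline, the
#' expected annual anomaly of year y is trend * (y - midpoint) +
#' extra * max(y - baseline_end, 0).
#'
#' @param params a [climate_gen_params()] object.
#' @return data frame `region_id`, `year`, `month`, `tmean_c`,
#'   `precip_mm`, with region metadata (mean temperature, trend, and a
#'   four-way region group used for attribution examples) in
#'   `attr(, "regions")`. Reproducible given `params$seed`.
#' @export
simulate_climate <- function(params = climate_gen_params()) {
  stopifnot(inherits(params, "climate_gen_params"))
  set.seed(params$seed)
  n <- params$n_regions
  years <- params$start_year:params$end_year
  mid <- (params$baseline_start + params$baseline_end) / 2

  region_id <- sprintf("R%03d", seq_len(n))
  mean_t <- stats::runif(n, 8, 28)
  extra <- rep(params$post_baseline_extra_trend, length.out = n)
  trend <- params$warming_trend
  if (is.null(trend)) {
    h_mean <- (0.56 - 6.5 * 0.03) / 21
    trend <- stats::runif(n, h_mean - 0.015, h_mean + 0.015)
  }
  trend <- rep(trend, length.out = n)
  group <- sample(c("Africa", "Americas", "Asia", "Europe"), n, replace = TRUE,
                  prob = c(0.35, 0.20, 0.30, 0.15))

  grid <- expand.grid(month = 1:12, year = years, region = seq_len(n),
                      KEEP.OUT.ATTRS = FALSE)
  shape <- rep(params$precip_gamma_shape, length.out = 12L)[grid$month]
  scale <- rep(params$precip_gamma_scale, length.out = 12L)[grid$month]
  tmean <- mean_t[grid$region] +
    params$seasonal_amplitude * cos(2 * pi * (grid$month - 7) / 12) +
    trend[grid$region] * (grid$year - mid) +
    extra[grid$region] * pmax(grid$year - params$baseline_end, 0) +
    stats::rnorm(nrow(grid), 0, params$temp_noise_sd)
  precip <- stats::rgamma(nrow(grid), shape = shape, scale = scale)
  precip[stats::runif(nrow(grid)) < params$zero_precip_prob] <- 0

  out <- data.frame(region_id = region_id[grid$region], year = grid$year,
                    month = grid$month, tmean_c = tmean, precip_mm = precip)
  out <- out[order(out$region_id, out$year, out$month), ]
  rownames(out) <- NULL
  attr(out, "regions") <- data.frame(region_id = region_id, mean_t = mean_t,
                                     trend = trend, extra_trend = extra,
                                     group = group)
  out
}

#' Parameters for the synthetic region-year outcome generator
#'
#' The true year-specific temperature-anomaly coefficients default to
#' the study's reported paths (moderate-to-severe 1.58 to 2.14, severe
#' 1.40 to 1.64 percentage points per degC over 2014-2019), the control
#' coefficients to the reported SHDI (-2.7 / -2.3 per 0.1 HDI) and
#' drought (0.014 / 0.011 per event-month) effects. Outcome noise
#' defaults to 0.05 pp, consistent with the precision of the reported
#' coefficient intervals at N = 83 regions and T = 6 years.
#'
#' @param lambda_path_msfi,lambda_path_sfi true anomaly coefficients per
#'   study year (pp per degC).
#' @param gamma_shdi_msfi,gamma_shdi_sfi SHDI coefficients (pp per 0.1
#'   HDI).
#' @param gamma_drought_msfi,gamma_drought_sfi drought coefficients (pp
#'   per event-month).
#' @param intercept_msfi,intercept_sfi mean region fixed effect (pp).
#' @param alpha_sd_msfi,alpha_sd_sfi sd of region fixed effects (pp).
#' @param noise_sd outcome noise sd (pp).
#' @param study_years years the outcome panel covers.
#' @param seed integer seed.
#' @export
panel_gen_params <- function(lambda_path_msfi = c(1.58, 1.71, 1.83, 1.94, 1.95, 2.14),
                             lambda_path_sfi = c(1.40, 1.54, 1.60, 1.61, 1.62, 1.64),
                             gamma_shdi_msfi = -2.7, gamma_shdi_sfi = -2.3,
                             gamma_drought_msfi = 0.014, gamma_drought_sfi = 0.011,
                             intercept_msfi = 35, intercept_sfi = 20,
                             alpha_sd_msfi = 4, alpha_sd_sfi = 2,
                             noise_sd = 0.05,
                             study_years = 2014:2019,
                             seed = 1L) {
  p <- list(lambda_path_msfi = lambda_path_msfi, lambda_path_sfi = lambda_path_sfi,
            gamma_shdi_msfi = gamma_shdi_msfi, gamma_shdi_sfi = gamma_shdi_sfi,
            gamma_drought_msfi = gamma_drought_msfi, gamma_drought_sfi = gamma_drought_sfi,
            intercept_msfi = intercept_msfi, intercept_sfi = intercept_sfi,
            alpha_sd_msfi = alpha_sd_msfi, alpha_sd_sfi = alpha_sd_sfi,
            noise_sd = noise_sd, study_years = as.integer(study_years),
            seed = as.integer(seed))
  t_n <- length(p$study_years)
  if (length(p$lambda_path_msfi) != t_n || length(p$lambda_path_sfi) != t_n) {
    stop("lambda paths must have one coefficient per study year")
  }
  if (p$noise_sd < 0 || p$alpha_sd_msfi < 0 || p$alpha_sd_sfi < 0) {
    stop("standard deviations must be non-negative")
  }
  class(p) <- "panel_gen_params"
  p
}

#' Simulate sub-national HDI trajectories
#'
#' Region base levels are uniform on [0.5, 0.7] with a slow upward
#' drift (0.003 per year) and small year-to-year noise, mimicking the
#' smooth within-sample variation of sub-national HDI.
#'
#' @param region_ids character vector of region ids.
#' @param years integer years.
#' @param seed integer seed.
#' @return data frame `region_id`, `year`, `shdi` in (0, 1).
#' @export
simulate_shdi <- function(region_ids, years, seed = 1L) {
  set.seed(seed)
  base <- stats::runif(length(region_ids), 0.5, 0.7)
  grid <- expand.grid(year = years, region = seq_along(region_ids),
                      KEEP.OUT.ATTRS = FALSE)
  shdi <- base[grid$region] + 0.003 * (grid$year - min(years)) +
    stats::rnorm(nrow(grid), 0, 0.005)
  out <- data.frame(region_id = region_ids[grid$region], year = grid$year,
                    shdi = pmin(pmax(shdi, 0.05), 0.95))
  out[order(out$region_id, out$year), ]
}

#' Simulate a region-year outcome panel from known truth
#'
#' Computes the climate covariates (annual anomaly, SPI-6 drought
#' counts, monthly anomaly bin counts) from the supplied climate series
#' and generates both prevalence outcomes from the linear time-varying
#' coefficient model: outcome = region effect + lambda_t * anomaly +
#' gamma_shdi * (SHDI / 0.1) + gamma_drought * drought + noise, clipped
#' to [0, 100], with the severe outcome constrained not to exceed the
#' moderate-to-severe outcome.
#'
#' @param climate monthly climate data frame from [simulate_climate()].
#' @param gen a [panel_gen_params()] object.
#' @param shdi optional data frame `region_id`, `year`, `shdi`;
#'   simulated with [simulate_shdi()] when `NULL`.
#' @param baseline anomaly/SPI baseline years.
#' @return region-year data frame with columns `region_id`, `year`,
#'   `anomaly`, `shdi`, `shdi_scaled` (= shdi/0.1), `drought`, the five
#'   bin-count columns, and true outcomes `msfi`, `sfi`. The generating
#'   truth (fixed effects and coefficient paths) is in
#'   `attr(, "truth")`.
#' @export
simulate_panel <- function(climate, gen = panel_gen_params(), shdi = NULL,
                           baseline = c(1981L, 2010L)) {
  stopifnot(inherits(gen, "panel_gen_params"))
  years <- gen$study_years
  if (min(climate$year) > baseline[1] || max(climate$year) < max(years)) {
    stop("climate series does not cover the baseline window plus study years")
  }
  anom <- annual_temperature_anomaly(climate, baseline)
  bins <- monthly_anomaly_bins(climate, baseline)
  dr <- drought_count(spi6(climate, calibration = baseline), years = years)

  panel <- anom[anom$year %in% years, c("region_id", "year", "anomaly")]
  panel <- merge(panel, bins, by = c("region_id", "year"))
  panel <- merge(panel, dr[, c("region_id", "year", "drought")],
                 by = c("region_id", "year"))
  regions <- sort(unique(panel$region_id))

  set.seed(gen$seed)
  if (is.null(shdi)) shdi <- simulate_shdi(regions, years, seed = gen$seed + 1L)
  panel <- merge(panel, shdi, by = c("region_id", "year"))
  panel$shdi_scaled <- panel$shdi / 0.1

  alpha_m <- stats::rnorm(length(regions), gen$intercept_msfi, gen$alpha_sd_msfi)
  alpha_s <- stats::rnorm(length(regions), gen$intercept_sfi, gen$alpha_sd_sfi)
  names(alpha_m) <- names(alpha_s) <- regions
  ti <- match(panel$year, years)
  mu_m <- alpha_m[panel$region_id] + gen$lambda_path_msfi[ti] * panel$anomaly +
    gen$gamma_shdi_msfi * panel$shdi_scaled + gen$gamma_drought_msfi * panel$drought
  mu_s <- alpha_s[panel$region_id] + gen$lambda_path_sfi[ti] * panel$anomaly +
    gen$gamma_shdi_sfi * panel$shdi_scaled + gen$gamma_drought_sfi * panel$drought
  msfi <- mu_m + stats::rnorm(nrow(panel), 0, gen$noise_sd)
  sfi <- mu_s + stats::rnorm(nrow(panel), 0, gen$noise_sd)
  panel$msfi <- pmin(pmax(msfi, 0), 100)
  panel$sfi <- pmin(panel$msfi, pmin(pmax(sfi, 0), 100))

  panel <- panel[order(panel$region_id, panel$year), ]
  rownames(panel) <- NULL
  attr(panel, "truth") <- list(alpha_msfi = alpha_m, alpha_sfi = alpha_s,
                               lambda_msfi = gen$lambda_path_msfi,
                               lambda_sfi = gen$lambda_path_sfi, gen = gen)
  panel
}

#' Simulate individual eight-item survey responses
#'
#' Each respondent draws a latent severity from a logistic distribution
#' whose location and scale are chosen, per region-year, so that the
#' probability of exceeding item-4's threshold equals the region-year's
#' true moderate-to-severe prevalence and the probability of exceeding
#' item-7's threshold equals the true severe prevalence. Item j is
#' affirmed iff the latent severity exceeds threshold j; with strictly
#' ascending thresholds this yields a deterministic Guttman response
#' pattern (affirming a harder item implies affirming all easier ones).
#' Survey weights are gamma-distributed with mean 1.
#'
#' @param panel region-year data frame with true `msfi` and `sfi`
#'   percent columns (from [simulate_panel()]).
#' @param item_thresholds 8 strictly ascending latent cutoffs.
#' @param respondents_per_region respondents per region-year.
#' @param seed integer seed.
#' @return data frame `region_id`, `year`, `weight`, `q1`..`q8`.
#' @export
simulate_fies_responses <- function(panel,
                                    item_thresholds = seq(-3.5, 3.5, by = 1),
                                    respondents_per_region = 800L,
                                    seed = 1L) {
  if (length(item_thresholds) != 8L || any(diff(item_thresholds) <= 0)) {
    stop("item_thresholds must be 8 strictly ascending values")
  }
  if (!all(c("region_id", "year", "msfi", "sfi") %in% names(panel))) {
    stop("panel must carry region_id, year, msfi, sfi")
  }
  set.seed(seed)
  n_rc <- as.integer(respondents_per_region)
  eps <- 1e-4
  pm <- pmin(pmax(panel$msfi / 100, eps), 1 - eps)
  ps <- pmin(pmax(panel$sfi / 100, eps), 1 - eps)
  ps <- pmin(ps, pm - 1e-6)
  lm_ <- stats::qlogis(pm)
  ls_ <- stats::qlogis(ps)
  scale <- (item_thresholds[7] - item_thresholds[4]) / pmax(lm_ - ls_, 1e-6)
  loc <- item_thresholds[4] + scale * lm_

  idx <- rep(seq_len(nrow(panel)), each = n_rc)
  latent <- stats::rlogis(length(idx), location = loc[idx], scale = scale[idx])
  q <- outer(latent, item_thresholds, `>`)
  storage.mode(q) <- "integer"
  colnames(q) <- paste0("q", 1:8)
  out <- data.frame(region_id = panel$region_id[idx], year = panel$year[idx],
                    weight = stats::rgamma(length(idx), shape = 4, rate = 4))
  cbind(out, as.data.frame(q))
}
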
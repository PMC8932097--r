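# Shared fixture builders. Everything is generated in code; no files.

# Monthly series with a fully controllable temperature function.
# f(region, year, month) -> degC; precipitation constant unless given.
make_climate <- function(regions = "A", years = 1981:2019,
                         temp_fun = function(r, y, m) 20,
                         precip_fun = function(r, y, m) 80) {
  g <- expand.grid(month = 1:12, year = years, region_id = regions,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$tmean_c <- mapply(temp_fun, g$region_id, g$year, g$month)
  g$precip_mm <- mapply(precip_fun, g$region_id, g$year, g$month)
  g[, c("region_id", "year", "month", "tmean_c", "precip_mm")]
}

# Small deterministic region-year panel with controllable outcome.
# outcome_fun(alpha_i, lambda_t, anomaly, shdi_scaled, drought) by row.
make_panel <- function(n_regions = 5, years = 2014:2019,
                       lambda = c(1.40, 1.54, 1.60, 1.61, 1.62, 1.64),
                       alpha = NULL, gamma_shdi = -2.3, gamma_drought = 0.011,
                       noise_sd = 0, seed = 1) {
  set.seed(seed)
  regions <- sprintf("R%02d", seq_len(n_regions))
  if (is.null(alpha)) alpha <- stats::rnorm(n_regions, 20, 2)
  g <- expand.grid(year = years, region_id = regions,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ti <- match(g$year, years)
  ri <- match(g$region_id, regions)
  g$anomaly <- 0.3 + 0.1 * ti + 0.25 * stats::rnorm(nrow(g))
  g$shdi_scaled <- stats::runif(nrow(g), 4.5, 7.5)
  g$drought <- stats::rpois(nrow(g), 0.5)
  g$sfi <- alpha[ri] + lambda[ti] * g$anomaly + gamma_shdi * g$shdi_scaled +
    gamma_drought * g$drought + stats::rnorm(nrow(g), 0, noise_sd)
  g$msfi <- g$sfi + 10
  g[, c("region_id", "year", "anomaly", "shdi_scaled", "drought", "msfi", "sfi")]
}

# Independent dummy-variable OLS oracle via explicit normal equations.
ols_oracle <- function(X, y) {
  qr.solve(crossprod(X), crossprod(X, y))
}
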
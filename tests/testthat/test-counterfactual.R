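test_that("trend-based counterfactual anomalies follow the explicit arithmetic", {
  # zero historical trend, factual equal to baseline climatology:
  # both anomalies 0
  cl0 <- make_climate(years = 1981:2019)
  sc0 <- counterfactual_anomaly(cl0)
  expect_true(all(abs(sc0$anomaly_factual) < 1e-10))
  expect_true(all(abs(sc0$anomaly_counterfactual) < 1e-10))

  # historical trend 0.01 degC/yr through 2010, then factual warming
  # 0.04 degC/yr from 2011: the 2019 gap is computed by hand
  cl <- make_climate(years = 1981:2019, temp_fun = function(r, y, m) {
    if (y <= 2010) 15 + 0.01 * (y - 1981) else 15 + 0.01 * (2010 - 1981) + 0.04 * (y - 2010)
  })
  sc <- counterfactual_anomaly(cl)
  bl_mean <- mean(15 + 0.01 * (1981:2010 - 1981))
  fact_2019 <- (15 + 0.01 * 29 + 0.04 * 9) - bl_mean
  cf_2019 <- (15 + 0.01 * (2019 - 1981)) - bl_mean
  r <- sc[sc$year == 2019, ]
  expect_equal(r$anomaly_factual, fact_2019, tolerance = 1e-8)
  expect_equal(r$anomaly_counterfactual, cf_2019, tolerance = 1e-8)
  expect_equal(r$anomaly_factual - r$anomaly_counterfactual, 0.03 * 9,
               tolerance = 1e-8)

  # an external override replaces the trend extrapolation
  ov <- sc0[, c("region_id", "year")]
  ov$anomaly_counterfactual <- 0.25
  sc_ov <- counterfactual_anomaly(cl0, override = ov)
  expect_true(all(sc_ov$anomaly_counterfactual == 0.25))
})

test_that("scenario predictions respect the linearity identity", {
  pan <- make_panel(n_regions = 8, noise_sd = 0.3, seed = 16)
  f <- fit_tvc(pan, "sfi")
  # scenario = factual anomalies reproduces in-sample fitted values
  pf <- predict_prevalence(f, pan, "anomaly")
  expect_equal(pf$predicted, unname(fitted(f$model)), tolerance = 1e-10)
  # linear model: prediction difference is exactly lambda_t * delta_V
  cf_anom <- pan$anomaly - 0.4
  pc <- predict_prevalence(f, pan, cf_anom)
  lam <- f$lambda$estimate[match(pan$year, f$lambda$year)]
  expect_equal(pf$predicted - pc$predicted, lam * 0.4, tolerance = 1e-10)
  # unknown region has no fixed effect
  pan_new <- pan
  pan_new$region_id[1] <- "ZZZ"
  expect_error(predict_prevalence(f, pan_new, "anomaly"), "absent from the fit")
})

test_that("toy attribution difference follows hand arithmetic", {
  # lambda = 2 every year, alpha = 10, no controls; V moves 1 -> 0.25
  years <- 2014:2019
  pan <- expand.grid(year = years, region_id = c("A", "B"),
                     stringsAsFactors = FALSE)
  set.seed(17)
  pan$anomaly <- runif(nrow(pan), 0.5, 1.5)
  pan$shdi_scaled <- 0
  pan$drought <- 0
  pan$sfi <- 10 + 2 * pan$anomaly
  pan$msfi <- 30 + 2 * pan$anomaly
  f_s <- suppressWarnings(fit_tvc(pan, "sfi", covariates = character(0),
                                  year_intercepts = FALSE))
  f_m <- suppressWarnings(fit_tvc(pan, "msfi", covariates = character(0),
                                  year_intercepts = FALSE))
  sc <- data.frame(region_id = pan$region_id, year = pan$year,
                   anomaly_factual = 1, anomaly_counterfactual = 0.25)
  gm <- data.frame(region_id = c("A", "B"), group = "G")
  at <- attribute(f_m, f_s, pan, sc, gm)
  expect_equal(at$sfi_difference, 2 * 0.75, tolerance = 1e-8)
  expect_equal(at$msfi_difference, 2 * 0.75, tolerance = 1e-8)

  # two regions with different gaps average with the given weights
  sc2 <- sc
  sc2$anomaly_counterfactual <- ifelse(sc2$region_id == "A", 0, 0.5)
  at2 <- attribute(f_m, f_s, pan, sc2, gm)
  expect_equal(at2$sfi_difference, mean(c(2 * 1, 2 * 0.5)), tolerance = 1e-8)
  wts <- data.frame(region_id = c("A", "B"), weight = c(3, 1))
  at3 <- attribute(f_m, f_s, pan, sc2, gm, group_weights = wts)
  expect_equal(at3$sfi_difference, (3 * 2 + 1 * 1) / 4, tolerance = 1e-8)
})

test_that("attribution is exactly linear in the coefficient path and scenario gap", {
  cl <- simulate_climate(climate_gen_params(n_regions = 12, seed = 18))
  pan <- simulate_panel(cl, panel_gen_params(seed = 19))
  fm <- fit_tvc(pan, "msfi")
  fs <- fit_tvc(pan, "sfi")
  sc <- counterfactual_anomaly(cl)
  gm <- attr(cl, "regions")[, c("region_id", "group")]
  at <- attribute(fm, fs, pan, sc, gm)

  # identity: group difference = weighted mean of lambda_t * delta_V
  p <- merge(merge(pan, sc, by = c("region_id", "year")), gm, by = "region_id")
  lam <- fs$lambda$estimate[match(p$year, fs$lambda$year)]
  manual <- tapply(lam * (p$anomaly_factual - p$anomaly_counterfactual), p$group, mean)
  expect_equal(at$sfi_difference, as.numeric(manual[at$group]), tolerance = 1e-8)
  # difference column is exactly factual - counterfactual
  expect_equal(at$sfi_difference, at$sfi_factual - at$sfi_counterfactual,
               tolerance = 1e-12)

  # identical scenarios zero every difference
  sc_same <- sc
  sc_same$anomaly_counterfactual <- sc_same$anomaly_factual
  at0 <- attribute(fm, fs, pan, sc_same, gm)
  expect_true(all(abs(at0$msfi_difference) < 1e-10))
  expect_true(all(abs(at0$sfi_difference) < 1e-10))

  # zeroed coefficient path zeroes the differences too
  fs0 <- fs
  fs0$model$coefficients[grep(":anomaly$", names(fs0$model$coefficients))] <- 0
  at_z <- attribute(fm, fs0, pan, sc, gm)
  expect_true(all(abs(at_z$sfi_difference) < 1e-10))

  # monotonicity: enlarging factual anomalies cannot shrink differences
  # when all coefficients are positive
  expect_true(all(fs$lambda$estimate > 0))
  sc_up <- sc
  sc_up$anomaly_factual <- sc_up$anomaly_factual + 0.3
  at_up <- attribute(fm, fs, pan, sc_up, gm)
  expect_true(all(at_up$sfi_difference >= at$sfi_difference - 1e-10))
})

test_that("published regional gaps come out of the attribution arithmetic", {
  tab <- attribution_table(reference_attribution_inputs())
  expect_equal(tab$msfi_difference[tab$group == "Africa"], 2.24, tolerance = 1e-9)
  expect_equal(tab$sfi_difference[tab$group == "Africa"], 0.88, tolerance = 1e-9)
  expect_equal(tab$msfi_difference[tab$group == "Europe"], 1.46, tolerance = 1e-9)
  expect_equal(tab$sfi_difference[tab$group == "Europe"], 0.19, tolerance = 1e-9)
})
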
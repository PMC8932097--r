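test_that("noiseless constant-coefficient panels are identified to machine precision", {
  pan <- make_panel(n_regions = 8, lambda = rep(2, 6), noise_sd = 0, seed = 3)
  f <- suppressWarnings(fit_fe_constant(pan, "sfi"))
  expect_equal(unname(f$beta$estimate[f$beta$term == "anomaly"]), 2,
               tolerance = 1e-10)
  expect_equal(unname(f$beta$estimate[f$beta$term == "shdi_scaled"]), -2.3,
               tolerance = 1e-10)
})

test_that("the within-type estimator equals independent dummy-variable OLS", {
  pan <- make_panel(n_regions = 5, lambda = rep(1.5, 6), noise_sd = 1, seed = 4)
  f <- fit_fe_constant(pan, "sfi")
  # oracle 1: explicit dummy design + normal equations
  X <- cbind(model.matrix(~ 0 + factor(pan$region_id)),
             model.matrix(~ factor(pan$year))[, -1],
             anomaly = pan$anomaly, shdi = pan$shdi_scaled, dr = pan$drought)
  b <- ols_oracle(X, pan$sfi)
  expect_equal(unname(f$beta$estimate[1]), unname(b["anomaly", 1]),
               tolerance = 1e-9)
  # oracle 2 (Frisch-Waugh): QR-project region and year dummies out of
  # outcome and covariates, then regress residuals on residuals
  D <- cbind(model.matrix(~ 0 + factor(pan$region_id)),
             model.matrix(~ factor(pan$year))[, -1])
  qD <- qr(D)
  ry <- qr.resid(qD, pan$sfi)
  rx <- cbind(qr.resid(qD, pan$anomaly), qr.resid(qD, pan$shdi_scaled),
              qr.resid(qD, pan$drought))
  bw <- ols_oracle(rx, ry)
  expect_equal(unname(f$beta$estimate), unname(as.numeric(bw)),
               tolerance = 1e-9)
})

test_that("time-varying fit recovers the generating path exactly without noise", {
  truth <- c(1.40, 1.54, 1.60, 1.61, 1.62, 1.64)
  pan <- make_panel(n_regions = 10, lambda = truth, noise_sd = 0, seed = 5)
  f <- suppressWarnings(fit_tvc(pan, "sfi"))
  expect_equal(f$lambda$estimate, truth, tolerance = 1e-9)
  expect_equal(unname(f$gamma$estimate), c(-2.3, 0.011), tolerance = 1e-9)
  expect_true(all(f$lambda$ci_low <= f$lambda$estimate &
                    f$lambda$estimate <= f$lambda$ci_high))
  # vcov symmetric PSD
  expect_equal(f$vcov, t(f$vcov), tolerance = 1e-10)
  expect_true(min(eigen(f$lambda_vcov, symmetric = TRUE,
                        only.values = TRUE)$values) > -1e-10)
})

test_that("per-year slopes equal independent per-year regressions on a pooled balanced panel", {
  pan <- make_panel(n_regions = 12, noise_sd = 1, seed = 6)
  pan$shdi_scaled <- 0
  pan$drought <- 0
  f <- fit_tvc(pan, "sfi", covariates = character(0), region_fe = FALSE)
  oracle <- vapply(sort(unique(pan$year)), function(y) {
    d <- pan[pan$year == y, ]
    unname(coef(lm(sfi ~ anomaly, data = d))["anomaly"])
  }, numeric(1))
  expect_equal(f$lambda$estimate, oracle, tolerance = 1e-10)
})

test_that("constraining the slopes equal reproduces the constant-coefficient fit", {
  pan <- make_panel(n_regions = 7, noise_sd = 0.8, seed = 7)
  fc <- fit_fe_constant(pan, "msfi")
  ft <- fit_tvc(pan, "msfi", time_varying = FALSE)
  expect_equal(unique(ft$lambda$estimate),
               fc$beta$estimate[fc$beta$term == "anomaly"], tolerance = 1e-12)
  expect_equal(unique(ft$lambda$se), fc$beta$se[fc$beta$term == "anomaly"],
               tolerance = 1e-12)
})

test_that("degenerate designs raise explicit errors", {
  pan <- make_panel(n_regions = 6, seed = 8)
  pan$anomaly[pan$year == 2016] <- 0.4
  expect_error(fit_tvc(pan, "sfi"), "zero cross-sectional variance.*2016")
  pan2 <- make_panel(n_regions = 6, seed = 9)
  pan2$shdi_scaled <- 1  # constant -> collinear with the fixed effects
  expect_error(fit_fe_constant(pan2, "sfi"), "collinear")
  pan3 <- make_panel(n_regions = 1, seed = 10)
  expect_error(fit_tvc(pan3, "sfi"), "at least 2")
})

test_that("cluster-robust covariance approaches the classical one under iid errors", {
  pan <- make_panel(n_regions = 150, lambda = rep(1.5, 6), noise_sd = 1, seed = 11)
  fcl <- fit_fe_constant(pan, "sfi", vcov_type = "cluster")
  fho <- fit_fe_constant(pan, "sfi", vcov_type = "classical")
  r <- fcl$beta$se[1] / fho$beta$se[1]
  expect_lt(abs(r - 1), 0.2)
})

test_that("binned regressions recover known bin coefficients and reject degenerate designs", {
  set.seed(12)
  n_regions <- 12
  years <- 2014:2019
  g <- expand.grid(year = years, region_id = sprintf("R%02d", 1:n_regions),
                   stringsAsFactors = FALSE)
  # random month allocations over the five bins
  counts <- t(rmultinom(nrow(g), 12, prob = c(0.3, 0.3, 0.2, 0.12, 0.08)))
  colnames(counts) <- anomaly_bin_labels()
  g <- cbind(g, as.data.frame(counts))
  g$shdi_scaled <- runif(nrow(g), 4.5, 7.5)
  g$drought <- rpois(nrow(g), 0.5)
  truth <- c(bin_lt02 = -0.009, bin_04_06 = 0.035, bin_06_08 = 0.044,
             bin_gt08 = 0.054)
  alpha <- rnorm(n_regions, 20, 2)
  g$sfi <- alpha[match(g$region_id, unique(g$region_id))] +
    as.matrix(g[, names(truth)]) %*% truth - 2.3 * g$shdi_scaled +
    0.011 * g$drought
  g$msfi <- g$sfi + 10

  fb <- suppressWarnings(fit_binned_constant(g, "sfi"))
  expect_equal(fb$coefficients$estimate[match(names(truth), fb$coefficients$bin)],
               unname(truth), tolerance = 1e-9)
  # time-varying variant also recovers a constant truth exactly
  fbt <- suppressWarnings(fit_binned_tvc(g, "sfi"))
  for (b in names(truth)) {
    expect_equal(fbt$coefficients$estimate[fbt$coefficients$bin == b],
                 rep(unname(truth[b]), length(years)), tolerance = 1e-8)
  }
  # sign/ordering pattern: low bin negative, higher bins increasing
  est <- fb$coefficients$estimate[match(names(truth), fb$coefficients$bin)]
  expect_lt(est[1], 0)
  expect_true(all(diff(est[2:4]) > 0))

  # single year: tvc and constant variants coincide (no region effects,
  # which a single cross-section cannot identify)
  g1 <- g[g$year == 2014, ]
  g1$sfi <- g1$sfi + rnorm(nrow(g1), 0, 0.5)
  f1t <- fit_binned_tvc(g1, "sfi", region_fe = FALSE)
  f1c <- fit_binned_constant(g1, "sfi", region_fe = FALSE)
  expect_equal(f1t$coefficients$estimate, f1c$coefficients$estimate,
               tolerance = 1e-10)

  # all months in the reference bin -> explicit error
  g0 <- g
  g0[, anomaly_bin_labels()] <- 0
  g0$bin_02_04 <- 12
  expect_error(fit_binned_tvc(g0, "sfi"), "reference bin")
})
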
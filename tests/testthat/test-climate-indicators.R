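test_that("annual anomaly is zero for a constant series and recovers imposed shifts", {
  cl <- make_climate()
  an <- annual_temperature_anomaly(cl)
  expect_true(all(abs(an$anomaly) < 1e-12))

  # baseline climatology in 1981-2010, uniformly +1.5 degC in 2019
  cl2 <- make_climate(temp_fun = function(r, y, m) {
    10 + 5 * cos(2 * pi * (m - 7) / 12) + if (y == 2019) 1.5 else 0
  })
  an2 <- annual_temperature_anomaly(cl2)
  expect_equal(an2$anomaly[an2$year == 2019], 1.5, tolerance = 1e-12)
  expect_true(all(abs(an2$anomaly[an2$year < 2019]) < 1e-12))
})

test_that("anomaly equivariance: adding a constant shifts every anomaly by it", {
  set.seed(11)
  base <- make_climate(regions = c("A", "B"),
                       temp_fun = function(r, y, m) 15 + rnorm(1))
  shifted <- base
  shifted$tmean_c <- shifted$tmean_c + 2.7
  a0 <- annual_temperature_anomaly(base)
  a1 <- annual_temperature_anomaly(shifted)
  expect_equal(a1$anomaly, a0$anomaly, tolerance = 1e-10)
})

test_that("baseline endpoints are inclusive and missing coverage errors name the region", {
  cl <- make_climate(years = 1981:2019)
  # removing any 2010 month must break the 1981-2010 baseline
  broken <- cl[!(cl$year == 2010 & cl$month == 12), ]
  expect_error(annual_temperature_anomaly(broken), "gaps in monthly coverage")
  short <- make_climate(years = 1985:2019)
  expect_error(annual_temperature_anomaly(short), "incomplete baseline.*A")
})

test_that("monthly anomaly bins follow half-open edges and sum to 12", {
  # anomalies cycle 0.1, 0.3, 0.5, 0.7, 0.9 over months of 2019 only;
  # calendar-month baselines are exact because 1981-2010 is constant
  offs <- rep(c(0.1, 0.3, 0.5, 0.7, 0.9), length.out = 12)
  cl <- make_climate(temp_fun = function(r, y, m) {
    20 + if (y == 2019) offs[m] else 0
  })
  bins <- monthly_anomaly_bins(cl)
  b19 <- bins[bins$year == 2019, ]
  # brute-force assignment oracle
  expected <- table(cut(offs, c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf), right = FALSE))
  expect_equal(unlist(b19[anomaly_bin_labels()], use.names = FALSE),
               as.integer(expected))
  counts <- as.matrix(bins[, anomaly_bin_labels()])
  expect_true(all(rowSums(counts) == 12L))

  # a zero-anomaly year lands entirely in the lowest bin
  b00 <- bins[bins$year == 2000, ]
  expect_equal(b00$bin_lt02, 12L)

  # boundary tie-break: exactly 0.4 goes to the 0.4-0.6 bin
  cl2 <- make_climate(temp_fun = function(r, y, m) 20 + if (y == 2019) 0.4 else 0)
  b2 <- monthly_anomaly_bins(cl2)
  expect_equal(b2$bin_04_06[b2$year == 2019], 12L)
})

test_that("SPI maps the calibration median to 0 and matches the closed-form gamma oracle", {
  set.seed(42)
  # 200 years of iid Gamma(2, scale 50) monthly precipitation, window 1:
  # fitted transform must match the true generating distribution closely
  cl <- make_climate(years = 1900:2099,
                     precip_fun = function(r, y, m) rgamma(1, 2, scale = 50))
  s <- spi(cl, calibration = c(1900L, 2099L), window = 1L)
  acc <- cl$precip_mm[order(cl$region_id, cl$year, cl$month)]
  oracle <- qnorm(pgamma(acc, 2, scale = 50))
  # per-calendar-month fits use 200 points each, so allow estimation
  # error of that order in the centre and more in the extreme tails
  expect_lt(median(abs(s$spi - oracle)), 0.1)
  expect_lt(unname(quantile(abs(s$spi - oracle), 0.99)), 0.35)
  expect_gt(cor(s$spi, oracle), 0.995)

  # an accumulation equal to the fitted median maps to ~0: check via
  # monotone interpolation around the empirical median month
  i <- which.min(abs(s$spi))
  expect_lt(abs(s$spi[i]), 0.1)
})

test_that("SPI is standard-normal over its calibration window and monotone in precipitation", {
  set.seed(7)
  cl <- make_climate(years = 1981:2019,
                     precip_fun = function(r, y, m) {
                       if (runif(1) < 0.05) 0 else rgamma(1, 2, scale = 40 + 3 * m)
                     })
  s <- spi6(cl)
  cal <- s$spi[s$year >= 1981 & s$year <= 2010 & !is.na(s$spi)]
  expect_lt(abs(mean(cal)), 0.05)
  expect_gt(sd(cal), 0.95)
  expect_lt(sd(cal), 1.05)

  # monotonicity: scale one month's accumulation up and SPI must not fall
  cl2 <- cl
  i <- cl2$year == 2015 & cl2$month == 3
  cl2$precip_mm[i] <- cl2$precip_mm[i] + 100
  s2 <- spi6(cl2)
  affected <- s2$year == 2015 & s2$month %in% 3:8
  expect_true(all(s2$spi[affected] >= s$spi[affected]))
})

test_that("vectorised gamma ML agrees with MASS::fitdistr", {
  set.seed(5)
  x <- rgamma(400, shape = 2.3, rate = 0.04)
  ours <- fiesclim:::.gamma_ml_by_group(x, rep("g", length(x)))
  ref <- MASS::fitdistr(x, "gamma", lower = c(1e-6, 1e-8))
  expect_equal(ours$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(ours$rate, unname(ref$estimate["rate"]), tolerance = 1e-3)
})

test_that("drought counts use a strict threshold and are monotone in it", {
  spi_df <- data.frame(region_id = "A", year = 2015, month = 1:12,
                       spi = c(-2, -1.6, -1.5, -1.4, rep(0, 8)))
  expect_equal(drought_count(spi_df)$drought, 2L)
  expect_equal(drought_count(spi_df, threshold = -1.4)$drought, 3L)
  expect_equal(drought_count(spi_df, threshold = -2.5)$drought, 0L)
  # non-increasing as the threshold decreases
  thresholds <- seq(-0.5, -2.5, by = -0.5)
  counts <- vapply(thresholds, function(th) drought_count(spi_df, th)$drought,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  # all-zero SPI -> no droughts
  zero <- data.frame(region_id = "A", year = 2015, month = 1:12, spi = 0)
  expect_equal(drought_count(zero)$drought, 0L)
})

test_that("grid aggregation takes weight-normalised means", {
  vals <- matrix(c(10, 20), nrow = 2, dimnames = list(c("c1", "c2"), "m1"))
  mask <- data.frame(region_id = "A", cell = c("c1", "c2"), weight = c(1, 3))
  expect_equal(unname(grid_to_region(vals, mask)["A", 1]), 17.5)
  # single-cell mask reproduces the cell series
  mask1 <- data.frame(region_id = "B", cell = "c2", weight = 2)
  expect_equal(unname(grid_to_region(vals, mask1)["B", 1]), 20)
  # uniform field is mask-invariant
  u <- matrix(4, 2, 3, dimnames = list(c("c1", "c2"), NULL))
  expect_true(all(grid_to_region(u, mask) == 4))
  expect_error(grid_to_region(vals, data.frame(region_id = "A", cell = "c1", weight = 0)),
               "empty")
})
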
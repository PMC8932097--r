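#' Climate indicator computations
#'
#' Functions that turn per-region monthly temperature and precipitation
#' series into the covariates used by the panel regressions: annual
#' temperature anomalies against a fixed baseline, counts of months per
#' anomaly bin, the six-month Standardized Precipitation Index (SPI-6),
#' and annual drought counts.
#'
#' @name indicators
NULL

# Validate a monthly climate table: region_id, year, month, tmean_c, precip_mm.
# Coverage must be contiguous monthly within each region's span.
.check_climate <- function(series, need_precip = FALSE) {
  need <- c("region_id", "year", "month", "tmean_c")
  if (need_precip) need <- c(need, "precip_mm")
  miss <- setdiff(need, names(series))
  if (length(miss) > 0L) {
    stop("climate series is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(series$month %in% 1:12)) stop("month must be in 1..12")
  if (need_precip && any(series$precip_mm < 0, na.rm = TRUE)) {
    stop("negative precipitation values are not allowed")
  }
  idx <- series$year * 12L + series$month
  reg <- as.character(series$region_id)
  ord <- order(reg, idx)
  same_region <- reg[ord][-1L] == reg[ord][-length(ord)]
  step <- diff(idx[ord])
  if (any(same_region & step == 0L)) {
    stop("duplicated (region, year, month) rows in climate series")
  }
  if (any(bad <- same_region & step != 1L)) {
    stop("climate series for region ",
         paste(unique(reg[ord][-1L][bad]), collapse = ", "),
         " has gaps in monthly coverage")
  }
  invisible(TRUE)
}

.check_baseline_coverage <- function(series, baseline) {
  bl <- series[series$year >= baseline[1] & series$year <= baseline[2], ]
  n_need <- 12L * (baseline[2] - baseline[1] + 1L)
  cnt <- table(bl$region_id)
  all_regions <- unique(series$region_id)
  bad <- all_regions[!(all_regions %in% names(cnt)) | cnt[as.character(all_regions)] != n_need]
  bad <- bad[!is.na(bad)]
  if (length(bad) > 0L) {
    stop("incomplete baseline coverage (", baseline[1], "-", baseline[2],
         ") for region(s): ", paste(bad, collapse = ", "))
  }
  invisible(bl)
}

#' Annual temperature anomaly against a fixed baseline
#'
#' The anomaly for year y is the mean of that year's 12 monthly
#' temperatures minus the mean of all monthly temperatures in the
#' baseline window (default 1981-2010, endpoints inclusive).
#'
#' @param series data frame with columns `region_id`, `year`, `month`,
#'   `tmean_c` (degrees Celsius); monthly coverage must include the full
#'   baseline window for every region.
#' @param baseline integer vector `c(first_year, last_year)` of the
#'   climatological baseline.
#' @return data frame with columns `region_id`, `year`, `anomaly` (degC),
#'   `n_months`, `complete`. Years with fewer than 12 months get `NA`
#'   anomaly and `complete = FALSE`.
#' @export
annual_temperature_anomaly <- function(series, baseline = c(1981L, 2010L)) {
  .check_climate(series)
  bl <- .check_baseline_coverage(series, baseline)
  bl_mean <- tapply(bl$tmean_c, bl$region_id, mean)

  key <- interaction(series$region_id, series$year, drop = TRUE)
  ann <- data.frame(
    region_id = tapply(as.character(series$region_id), key, `[`, 1L),
    year = as.integer(tapply(series$year, key, `[`, 1L)),
    mean_t = as.numeric(tapply(series$tmean_c, key, mean)),
    n_months = as.integer(tapply(series$tmean_c, key, length)),
    row.names = NULL
  )
  ann$anomaly <- ann$mean_t - as.numeric(bl_mean[ann$region_id])
  ann$complete <- ann$n_months == 12L
  ann$anomaly[!ann$complete] <- NA_real_
  ann <- ann[order(ann$region_id, ann$year), c("region_id", "year", "anomaly", "n_months", "complete")]
  rownames(ann) <- NULL
  ann
}

#' Labels of the monthly-anomaly bins
#'
#' Five bins of monthly temperature anomaly (degC): below 0.2,
#' 0.2-0.4 (the regression reference bin), 0.4-0.6, 0.6-0.8 and above
#' 0.8. Interior edges are half-open [a, b), so an anomaly of exactly
#' 0.4 falls in the 0.4-0.6 bin.
#'
#' @return character vector of the five bin column names, in order.
#' @export
anomaly_bin_labels <- function() {
  c("bin_lt02", "bin_02_04", "bin_04_06", "bin_06_08", "bin_gt08")
}

#' Months per year in each monthly-anomaly bin
#'
#' Monthly anomalies are computed against calendar-month-specific
#' baseline means (otherwise the seasonal cycle, not climate change,
#' would drive bin membership). Each month falls in exactly one bin;
#' counts over complete years sum to 12.
#'
#' @inheritParams annual_temperature_anomaly
#' @param edges interior bin edges in degC.
#' @return data frame: `region_id`, `year`, one integer column per bin
#'   (see [anomaly_bin_labels()]).
#' @export
monthly_anomaly_bins <- function(series, baseline = c(1981L, 2010L),
                                 edges = c(0.2, 0.4, 0.6, 0.8)) {
  .check_climate(series)
  bl <- .check_baseline_coverage(series, baseline)
  ckey <- paste(bl$region_id, bl$month)
  clim <- tapply(bl$tmean_c, ckey, mean)
  anom <- series$tmean_c - as.numeric(clim[paste(series$region_id, series$month)])
  # bin membership is decided on anomalies rounded to 1e-9 degC so that
  # values sitting exactly on an edge are not moved across it by
  # floating-point summation error
  anom <- round(anom, 9)
  labs <- anomaly_bin_labels()
  bin <- cut(anom, breaks = c(-Inf, edges, Inf), right = FALSE, labels = labs)

  key <- interaction(series$region_id, series$year, drop = TRUE)
  counts <- table(key, bin)
  out <- data.frame(
    region_id = tapply(as.character(series$region_id), key, `[`, 1L),
    year = as.integer(tapply(series$year, key, `[`, 1L)),
    row.names = NULL
  )
  m <- counts[match(as.character(interaction(out$region_id, out$year, drop = TRUE)), rownames(counts)), , drop = FALSE]
  for (lab in labs) out[[lab]] <- as.integer(m[, lab])
  out <- out[order(out$region_id, out$year), ]
  rownames(out) <- NULL
  out
}

# Vectorised maximum-likelihood gamma fit by group.
# Solves log(k) - digamma(k) = log(mean) - mean(log) with a Thom-type
# initialiser refined by Newton steps; method-of-moments fallback when
# the profile equation is degenerate (A <= 0) or the group is tiny.
.gamma_ml_by_group <- function(x, group) {
  group <- factor(group)
  n <- as.numeric(tapply(x, group, length))
  m <- as.numeric(tapply(x, group, mean))
  ml <- as.numeric(tapply(log(x), group, mean))
  v <- as.numeric(tapply(x, group, stats::var))
  a <- log(m) - ml

  shape <- rep(NA_real_, length(m))
  ok <- is.finite(a) & a > 0 & n >= 3
  if (any(ok)) {
    k <- (1 + sqrt(1 + 4 * a[ok] / 3)) / (4 * a[ok])
    for (i in 1:30) {
      f <- log(k) - digamma(k) - a[ok]
      fp <- 1 / k - trigamma(k)
      step <- f / fp
      k <- pmax(k - step, k / 10)
    }
    shape[ok] <- k
  }
  mom <- !ok & is.finite(v) & v > 0
  shape[mom] <- m[mom]^2 / v[mom]
  rate <- shape / m
  data.frame(group = levels(group), n = n, shape = shape, rate = rate,
             stringsAsFactors = FALSE)
}

#' Standardized Precipitation Index
#'
#' Accumulates precipitation over a trailing window (default 6 months,
#' ending at the indexed month), fits a calendar-month-specific gamma
#' distribution with an explicit point mass at zero to the accumulations
#' inside the calibration window, and maps each accumulation x to
#' `qnorm(q + (1 - q) * pgamma(x))` where q is the calibration share of
#' zero accumulations. Months outside the calibration window are
#' transformed with the calibration parameters. SPI is monotone
#' non-decreasing in accumulated precipitation by construction.
#'
#' @param series data frame with `region_id`, `year`, `month`,
#'   `precip_mm` (>= 0).
#' @param calibration `c(first_year, last_year)` of the calibration
#'   window (default 1981-2010, aligned with the anomaly baseline).
#' @param window accumulation length in months.
#' @return data frame `region_id`, `year`, `month`, `spi`. SPI is `NA`
#'   for months whose accumulation is undefined (start of series) or
#'   whose calendar month has an all-zero calibration sample (flagged
#'   with a warning).
#' @export
spi <- function(series, calibration = c(1981L, 2010L), window = 6L) {
  .check_climate(series, need_precip = TRUE)
  ord <- order(series$region_id, series$year, series$month)
  s <- series[ord, ]

  # split() orders groups by factor level, which matches the row sort above
  acc <- unlist(lapply(split(s$precip_mm, factor(s$region_id)), function(p) {
    as.numeric(stats::filter(p, rep(1, window), sides = 1))
  }), use.names = FALSE)
  s$acc <- acc

  cal <- !is.na(s$acc) & s$year >= calibration[1] & s$year <= calibration[2]
  if (!any(cal)) stop("no accumulations fall inside the calibration window")
  gkey <- paste(s$region_id, s$month, sep = "|")
  calkey <- gkey[cal]
  q0 <- tapply(s$acc[cal] == 0, calkey, mean)

  pos <- cal & s$acc > 0
  fits <- .gamma_ml_by_group(s$acc[pos], gkey[pos])
  idx <- match(gkey, fits$group)
  shape <- fits$shape[idx]
  rate <- fits$rate[idx]
  q <- as.numeric(q0[gkey])

  dead <- !is.na(q) & q >= 1
  if (any(dead)) {
    warning("all-zero calibration accumulations for ",
            length(unique(gkey[dead])),
            " (region, calendar month) cell(s); SPI set to NA there")
  }
  h <- q + (1 - q) * stats::pgamma(s$acc, shape = shape, rate = rate)
  h[s$acc == 0 & !is.na(s$acc)] <- q[s$acc == 0 & !is.na(s$acc)]
  h <- pmin(pmax(h, 1e-7), 1 - 1e-7)
  out <- data.frame(region_id = s$region_id, year = s$year, month = s$month,
                    spi = stats::qnorm(h))
  out$spi[is.na(s$acc) | is.na(shape) | dead] <- NA_real_
  out <- out[order(out$region_id, out$year, out$month), ]
  rownames(out) <- NULL
  out
}

#' Six-month SPI
#'
#' Convenience wrapper for [spi()] with the 6-month accumulation window
#' used as the drought indicator throughout the package.
#' @inheritParams spi
#' @export
spi6 <- function(series, calibration = c(1981L, 2010L)) {
  spi(series, calibration = calibration, window = 6L)
}

#' Annual drought count from an SPI series
#'
#' Counts, per region and year, the months in which SPI falls strictly
#' below the threshold (default -1.5).
#'
#' @param spi_series data frame as returned by [spi6()].
#' @param threshold drought threshold on the SPI scale.
#' @param years optional years to restrict to.
#' @return data frame `region_id`, `year`, `drought`, `n_spi_missing`.
#'   Missing SPI months are excluded from the count and reported in
#'   `n_spi_missing` (a partial count, flagged, not an error).
#' @export
drought_count <- function(spi_series, threshold = -1.5, years = NULL) {
  if (!all(c("region_id", "year", "spi") %in% names(spi_series))) {
    stop("spi_series must have columns region_id, year, spi")
  }
  s <- spi_series
  if (!is.null(years)) s <- s[s$year %in% years, ]
  key <- paste(s$region_id, s$year, sep = "\r")
  below <- rowsum(as.numeric(!is.na(s$spi) & s$spi < threshold), key)
  miss <- rowsum(as.numeric(is.na(s$spi)), key)
  parts <- strsplit(rownames(below), "\r", fixed = TRUE)
  out <- data.frame(
    region_id = vapply(parts, `[`, "", 1L),
    year = as.integer(vapply(parts, `[`, "", 2L)),
    drought = as.integer(below[, 1L]),
    n_spi_missing = as.integer(miss[, 1L]),
    row.names = NULL
  )
  out <- out[order(out$region_id, out$year), ]
  rownames(out) <- NULL
  out
}

#' Aggregate gridded cell values to regions
#'
#' Computes, for each region, the weight-normalised mean of cell values,
#' applied column-wise (columns are typically months).
#'
#' @param cell_values numeric matrix, one row per grid cell (rownames =
#'   cell ids), one column per time step.
#' @param mask data frame `region_id`, `cell`, `weight` (weights >= 0,
#'   at least one positive weight per region).
#' @return matrix with one row per region (rownames = region ids).
#' @export
grid_to_region <- function(cell_values, mask) {
  if (!all(c("region_id", "cell", "weight") %in% names(mask))) {
    stop("mask must have columns region_id, cell, weight")
  }
  if (any(mask$weight < 0)) stop("mask weights must be non-negative")
  regions <- unique(as.character(mask$region_id))
  out <- matrix(NA_real_, nrow = length(regions), ncol = ncol(cell_values),
                dimnames = list(regions, colnames(cell_values)))
  for (r in regions) {
    mr <- mask[mask$region_id == r, ]
    rows <- match(as.character(mr$cell), rownames(cell_values))
    if (anyNA(rows)) stop("mask for region ", r, " references unknown cell(s)")
    w <- mr$weight
    if (sum(w) <= 0) stop("region ", r, " has an empty (all-zero-weight) mask")
    out[r, ] <- colSums(cell_values[rows, , drop = FALSE] * w) / sum(w)
  }
  out
}
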
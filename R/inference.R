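# Rebuild a tvc fit's non-fixed-effect design with region effects
# absorbed by demeaning (exact Frisch-Waugh), and return the
# leave-one-region-out jackknife covariance of the lambda block.
# Coefficients of the demeaned system equal the fit's, which is
# asserted.
.lambda_jackknife <- function(fit) {
  df <- fit$data
  region_f <- df$region_f
  year_f <- df$year_f
  years <- levels(year_f)
  t_n <- length(years)
  yr_d <- stats::model.matrix(~ 0 + year_f)
  has_year_fe <- length(fit$year_effects) > 0L
  has_region_fe <- length(fit$alpha_hat) > 0L
  covars <- fit$covariates
  X <- cbind(if (has_year_fe) yr_d[, -1L, drop = FALSE],
             yr_d * df$anomaly,
             if (length(covars)) as.matrix(df[, covars, drop = FALSE]))
  li <- (if (has_year_fe) t_n - 1L else 0L) + seq_len(t_n)
  if (has_region_fe) {
    dm <- function(v) v - stats::ave(v, region_f)
    X <- apply(X, 2L, dm)
    y <- dm(df$.y)
  } else {
    X <- cbind(1, X)
    li <- li + 1L
    y <- df$.y
  }
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  b <- solve(XtX, Xty)
  stopifnot(max(abs(b[li] - fit$lambda$estimate)) < 1e-6)
  G <- nlevels(region_f)
  rows <- split(seq_len(nrow(X)), region_f)
  lj <- vapply(rows, function(i) {
    Xg <- X[i, , drop = FALSE]
    as.numeric(solve(XtX - crossprod(Xg), Xty - crossprod(Xg, y[i]))[li])
  }, numeric(t_n))
  V <- (G - 1) / G * tcrossprod(lj - rowMeans(lj))
  list(vcov = V, n_clusters = G)
}

#' Sequential Wald tests for an increasing coefficient path
#'
#' For each consecutive pair of study years tests H0: lambda_t =
#' lambda_{t-1} against H1: lambda_t > lambda_{t-1}: statistic =
#' (l_t - l_{t-1}) / se(difference) using the joint covariance of the
#' year-specific coefficients, with a one-sided p-value.
#'
#' By default the pair-difference covariance comes from a
#' leave-one-region-out cluster jackknife of the coefficient path and
#' the statistic is referred to t(G - 1), G the number of region
#' clusters; this combination holds close-to-nominal size at the
#' study's scale. `vcov = "analytic"` instead uses the fit's stored
#' (plug-in cluster-robust) covariance with a normal reference.
#'
#' @param fit a [fit_tvc()] object.
#' @param adjust `"none"` (default; pairs are reported individually) or
#'   `"bonferroni"`.
#' @param vcov `"jackknife"` (default) or `"analytic"`.
#' @return data frame `year_from`, `year_to`, `diff`, `se`, `statistic`,
#'   `p`.
#' @export
wald_sequential_test <- function(fit, adjust = c("none", "bonferroni"),
                                 vcov = c("jackknife", "analytic")) {
  adjust <- match.arg(adjust)
  vcov <- match.arg(vcov)
  if (!inherits(fit, "tvc_fit")) stop("fit must come from fit_tvc()")
  if (is.null(fit$lambda_vcov)) stop("fit carries no coefficient covariance")
  lam <- fit$lambda$estimate
  t_n <- length(lam)
  if (t_n < 2L) stop("need at least two years of coefficients")
  if (isFALSE(fit$time_varying) || isTRUE(fit$time_varying_controls)) {
    # the jackknife helper rebuilds the saturated anomaly-by-year design
    vcov <- "analytic"
  }
  if (vcov == "jackknife") {
    jk <- .lambda_jackknife(fit)
    V <- jk$vcov
    pfun <- function(z) stats::pt(z, df = jk$n_clusters - 1L, lower.tail = FALSE)
  } else {
    V <- fit$lambda_vcov
    pfun <- function(z) stats::pnorm(z, lower.tail = FALSE)
  }
  i <- seq_len(t_n - 1L)
  d <- lam[i + 1L] - lam[i]
  se <- sqrt(diag(V)[i + 1L] + diag(V)[i] - 2 * V[cbind(i + 1L, i)])
  z <- d / se
  p <- pfun(z)
  if (adjust == "bonferroni") p <- pmin(p * (t_n - 1L), 1)
  data.frame(year_from = fit$years[i], year_to = fit$years[i + 1L],
             diff = unname(d), se = unname(se), statistic = unname(z), p = unname(p))
}

#' Test whether the anomaly effect differs across the two outcomes
#'
#' Tests the joint null that the year-specific anomaly coefficient
#' paths for moderate-to-severe and severe food insecurity are equal.
#' Because both outcomes are observed on the same (region, year) keys
#' and share one design, the stacked seemingly-unrelated system with
#' outcome-specific coefficients reduces exactly (Frisch-Waugh) to a
#' single regression of the outcome difference (msfi - sfi) on the
#' common design: the coefficient-path difference is that regression's
#' anomaly-by-year coefficient vector, and cross-equation error
#' correlation within a region is absorbed by the differenced error.
#'
#' Two covariance flavours are available for the path difference.
#' `"classical"` (the default) is the exact OLS F test on the
#' difference regression: differencing the outcomes cancels any
#' region-level shock that moves both severities together, and the
#' remaining idiosyncratic error makes F(q, n - G - k) exact under
#' independence. `"jackknife"` estimates the covariance by a
#' leave-one-region-out cluster jackknife and refers the Wald form to a
#' Hotelling-type F(q, G - q) (use when the differenced errors are
#' still believed dependent within regions; note that plug-in cluster
#' Wald tests with q = 6 restrictions and ~80 clusters measurably
#' over-reject, which is why the plain clustered statistic is not
#' offered here).
#'
#' @param fit_msfi,fit_sfi [fit_tvc()] objects for the two outcomes
#'   (used for configuration checks; the difference system is refit
#'   internally).
#' @param panel region-year data frame carrying both `msfi` and `sfi`
#'   outcome columns on identical (region, year) keys.
#' @param covariates control columns (constant coefficients per
#'   outcome).
#' @param vcov `"classical"` (exact F under independent errors) or
#'   `"jackknife"` (cluster-robust).
#' @return list with `statistic` (Wald quadratic form), `df` (= number
#'   of years q), `p_value`, `p_chisq` (chi-squared reference, for
#'   comparison), `per_year` (per-year path differences with standard
#'   errors), `n_clusters`.
#' @export
heterogeneity_test <- function(fit_msfi, fit_sfi, panel,
                               covariates = c("shdi_scaled", "drought"),
                               vcov = c("classical", "jackknife")) {
  vcov <- match.arg(vcov)
  if (!inherits(fit_msfi, "tvc_fit") || !inherits(fit_sfi, "tvc_fit")) {
    stop("fits must come from fit_tvc()")
  }
  need <- c("region_id", "year", "msfi", "sfi", "anomaly", covariates)
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0L) stop("panel missing column(s): ", paste(miss, collapse = ", "))
  df <- panel[stats::complete.cases(panel[, need]), need]
  if (anyDuplicated(paste(df$region_id, df$year))) {
    stop("duplicated (region, year) keys in panel")
  }
  if (!identical(sort(unique(df$year)), sort(unique(fit_msfi$years)))) {
    stop("panel years do not match the fitted years (key-alignment error)")
  }

  region_f <- factor(df$region_id)
  year_f <- factor(df$year)
  years <- levels(year_f)
  t_n <- length(years)
  G <- nlevels(region_f)

  # difference regression, region fixed effects removed by group
  # demeaning (exact projection on the region dummies)
  yr_d <- stats::model.matrix(~ 0 + year_f)
  X <- cbind(yr_d[, -1L, drop = FALSE], yr_d * df$anomaly,
             as.matrix(df[, covariates, drop = FALSE]))
  colnames(X) <- c(paste0("tau_", years[-1L]), paste0("lambda_", years),
                   covariates)
  dm <- function(v) v - stats::ave(v, region_f)
  Xd <- apply(X, 2L, dm)
  yd <- dm(df$msfi - df$sfi)

  XtX <- crossprod(Xd)
  if (qr(XtX)$rank < ncol(Xd)) stop("difference design is rank deficient")
  b <- solve(XtX, crossprod(Xd, yd))
  li <- match(paste0("lambda_", years), colnames(X))
  d <- as.numeric(b[li])

  quad <- function(Vd, d) {
    W <- if (all(is.finite(Vd)) && kappa(Vd) < 1e10) {
      as.numeric(t(d) %*% solve(Vd, d))
    } else {
      as.numeric(t(d) %*% MASS::ginv(Vd) %*% d)
    }
    max(W, 0)
  }
  if (vcov == "classical") {
    e <- yd - Xd %*% b
    # residual df: demeaned regressors plus the absorbed region effects
    df_resid <- nrow(Xd) - ncol(Xd) - (G - 1L)
    s2 <- sum(e^2) / df_resid
    if (s2 <= .Machine$double.eps) {
      # zero residual variance: identical outcomes carry no evidence
      # against the null, a noiseless nonzero difference is decisive
      Vd <- diag(t_n) * 0
      W <- if (max(abs(d)) < 1e-10) 0 else Inf
    } else {
      Vd <- s2 * solve(XtX)[li, li]
      W <- quad(Vd, d)
    }
    p_value <- stats::pf(W / t_n, t_n, df_resid, lower.tail = FALSE)
  } else {
    # leave-one-region-out jackknife for the path-difference covariance
    rows <- split(seq_len(nrow(Xd)), region_f)
    d_jack <- vapply(rows, function(i) {
      Xg <- Xd[i, , drop = FALSE]
      bt <- solve(XtX - crossprod(Xg),
                  crossprod(Xd, yd) - crossprod(Xg, yd[i]))
      as.numeric(bt[li])
    }, numeric(t_n))
    dbar <- rowMeans(d_jack)
    Vd <- (G - 1) / G * tcrossprod(d_jack - dbar)
    W <- quad(Vd, d)
    p_value <- if (G > t_n + 1L) {
      stats::pf(W * (G - t_n) / (t_n * (G - 1)), t_n, G - t_n, lower.tail = FALSE)
    } else {
      warning("too few region clusters (", G, ") for ", t_n,
              " restrictions; falling back to the chi-squared reference")
      stats::pchisq(W, df = t_n, lower.tail = FALSE)
    }
  }
  list(statistic = W, df = t_n,
       p_value = p_value,
       p_chisq = stats::pchisq(W, df = t_n, lower.tail = FALSE),
       per_year = data.frame(year = as.integer(years), diff = d,
                             se = sqrt(pmax(diag(Vd), 0)), row.names = NULL),
       n_clusters = G)
}
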
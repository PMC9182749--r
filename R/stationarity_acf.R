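# Window-width selection from the heart-rate autocorrelation function:
# polynomial detrending, augmented Dickey-Fuller stationarity gate, sample
# ACF with Bartlett large-lag confidence bounds, cutoff-lag extraction, and
# multi-session aggregation into the sliding-window width.

#' Polynomial detrending
#'
#' Subtracts the least-squares polynomial of the given order fitted against
#' time.
#'
#' @param series A [uniform_series()].
#' @param order Polynomial order (default 1).
#' @return A [uniform_series()] of residuals (mean approximately 0).
#' @export
detrend_poly <- function(series, order = 1) {
  stopifnot(inherits(series, "uniform_series"), order >= 0)
  x <- series$values
  if (length(x) <= order + 1)
    stop("series too short to fit a polynomial of order ", order)
  tt <- (seq_along(x) - 1) / length(x)          # scaled time, conditioning
  X <- outer(tt, 0:order, `^`)
  fit <- stats::lm.fit(X, x)
  uniform_series(as.numeric(fit$residuals), t0 = series$t0, dt = series$dt)
}

# Classical tau_mu (regression with constant, no trend) percentiles of the
# Dickey-Fuller distribution, by sample size; used to interpolate p-values.
.adf_tau_mu <- list(
  probs = c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99),
  n = c(25, 50, 100, 250, 500, 1e5),
  table = rbind(
    c(-3.75, -3.33, -3.00, -2.62, -0.37,  0.00,  0.34,  0.72),
    c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03,  0.29,  0.66),
    c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05,  0.26,  0.63),
    c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06,  0.24,  0.62),
    c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07,  0.24,  0.61),
    c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07,  0.23,  0.60)))

#' Augmented Dickey-Fuller test for stationarity
#'
#' Unit-root test with a constant (series are detrended beforehand, so no
#' trend term is included).  Regresses the first difference on the lagged
#' level and `k` lagged differences; the t-statistic of the lagged level is
#' compared against the classical constant-case Dickey-Fuller percentile
#' table (p-values interpolated, clamped to [0.01, 0.99]).
#'
#' A constant series contains no unit root by construction: it is reported as
#' stationary with statistic `-Inf` and p-value 0.01.
#'
#' @param series A [uniform_series()] with at least 20 samples.
#' @param k Number of lagged differences; default `trunc((n - 1)^(1/3))`.
#' @param alpha Rejection level for the stationarity flag (default 0.05).
#' @return List with `statistic`, `p_value`, `stationary` (logical), `k`.
#' @export
adf_test <- function(series, k = NULL, alpha = 0.05) {
  stopifnot(inherits(series, "uniform_series"))
  y <- series$values
  n <- length(y)
  if (n < 20) stop("need >= 20 samples for the Dickey-Fuller test")
  if (stats::sd(y) == 0)
    return(list(statistic = -Inf, p_value = 0.01, stationary = TRUE, k = 0L))
  if (is.null(k)) k <- trunc((n - 1)^(1 / 3))
  k <- max(0L, as.integer(k))
  dy <- diff(y)
  m <- length(dy) - k
  yl <- y[(k + 1):(n - 1)]                       # lagged level
  X <- cbind(1, yl)
  if (k > 0)
    for (j in seq_len(k)) X <- cbind(X, dy[(k + 1 - j):(length(dy) - j)])
  resp <- dy[(k + 1):length(dy)]
  fit <- stats::lm.fit(X, resp)
  res <- fit$residuals
  dfree <- m - ncol(X)
  sigma2 <- sum(res^2) / dfree
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtX_inv[2, 2])
  stat <- fit$coefficients[2] / se
  tab <- .adf_tau_mu
  row <- vapply(seq_along(tab$probs), function(j)
    stats::approx(tab$n, tab$table[, j], xout = min(n, max(tab$n)),
                  rule = 2)$y, numeric(1))
  p <- stats::approx(row, tab$probs, xout = stat, rule = 2)$y
  list(statistic = unname(stat), p_value = p, stationary = p < alpha,
       k = k)
}

#' Sample autocorrelation with Bartlett confidence bounds
#'
#' ACF normalized by the lag-0 autocovariance; the confidence band is the
#' Bartlett large-lag standard error `sqrt((1 + 2 * sum_{j<k} r_j^2) / n)`
#' scaled by the two-sided normal quantile at level `alpha`, symmetric about
#' zero.
#'
#' @param series A detrended, stationary [uniform_series()].
#' @param max_lag_s Largest lag in seconds (must be below the series span).
#' @param alpha Confidence level parameter (default 0.05).
#' @return An object of class `acf_result` with fields `dt`, `lags` (s),
#'   `acf`, `ci_upper`, `ci_lower`, `alpha`, `n`, `t_cut` (NA until
#'   [cutoff_lag()] is applied).
#' @export
acf_bartlett <- function(series, max_lag_s = 300, alpha = 0.05) {
  stopifnot(inherits(series, "uniform_series"))
  n <- length(series$values)
  max_lag <- floor(max_lag_s / series$dt)
  if (max_lag >= n)
    stop("'max_lag_s' must be smaller than the series span")
  if (max_lag < 1) stop("'max_lag_s' smaller than one sampling step")
  r <- as.numeric(stats::acf(series$values, lag.max = max_lag,
                             plot = FALSE, demean = TRUE)$acf)
  # Bartlett SE at lag k uses autocorrelations below k (lag 1 -> 1/sqrt(n)).
  cum <- cumsum(r[-1]^2)
  se <- sqrt((1 + 2 * c(0, cum[-length(cum)])) / n)
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(dt = series$dt,
                 lags = (0:max_lag) * series$dt,
                 acf = r,
                 ci_upper = c(NA_real_, z * se),
                 ci_lower = c(NA_real_, -z * se),
                 alpha = alpha, n = n, t_cut = NA_real_),
            class = "acf_result")
}

#' @export
print.acf_result <- function(x, ...) {
  cat(sprintf("<acf_result: %d lags (dt = %g s), alpha = %g, t_cut = %s>\n",
              length(x$lags) - 1L, x$dt, x$alpha,
              if (is.na(x$t_cut)) "NA" else sprintf("%g s", x$t_cut)))
  invisible(x)
}

#' Diagnostic plot of the ACF, Bartlett bounds and cutoff point
#'
#' @param x An `acf_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.acf_result <- function(x, ...) {
  graphics::plot(x$lags, x$acf, type = "h", xlab = "lag (s)", ylab = "ACF",
                 ...)
  graphics::lines(x$lags[-1], x$ci_upper[-1], col = "blue", lty = 2)
  graphics::lines(x$lags[-1], x$ci_lower[-1], col = "blue", lty = 2)
  if (!is.na(x$t_cut)) {
    yb <- stats::approx(x$lags[-1], x$ci_upper[-1], xout = x$t_cut,
                        rule = 2)$y
    graphics::points(x$t_cut, yb, col = "red", pch = 19)
  }
  invisible(x)
}

#' Cutoff lag: first crossing of the ACF below the upper Bartlett bound
#'
#' The cutoff is the smallest lag at which the ACF reaches the upper
#' confidence bound, located by linear interpolation between the bracketing
#' integer lags.  If the ACF at lag 1 is already below the bound the cutoff
#' is one sampling step.
#'
#' @param acf_result An [acf_bartlett()] result.
#' @return Cutoff lag `t_cut` in seconds.
#' @export
cutoff_lag <- function(acf_result) {
  stopifnot(inherits(acf_result, "acf_result"))
  f <- acf_result$acf - acf_result$ci_upper   # f[1] is NA (lag 0)
  K <- length(f)
  if (K < 2) stop("ACF has no positive lags")
  if (f[2] <= 0) return(acf_result$dt)
  for (k in 3:K) {
    if (f[k] <= 0) {
      frac <- f[k - 1] / (f[k - 1] - f[k])
      return(acf_result$lags[k - 1] + frac * acf_result$dt)
    }
  }
  stop("ACF never crosses the upper confidence bound within max_lag; ",
       "increase 'max_lag_s'")
}

#' Estimate the analysis window width over a set of sessions
#'
#' For each session the heart-rate channel is resampled to the uniform grid,
#' detrended (order `detrend_order`; escalated once to order 2 if the
#' Dickey-Fuller gate fails), gated for stationarity, and its ACF cutoff lag
#' extracted.  The window width is the mean cutoff rounded to the nearest
#' 10 s; when 90 s lies within one SD of the mean the conventional 90 s
#' width is adopted.  An explicit `override_s` wins over the estimate.
#'
#' @param sessions List of [run_session()] objects.
#' @param dt Grid step in seconds.
#' @param detrend_order Initial detrending order (default 1).
#' @param max_lag_s Largest ACF lag in seconds.
#' @param alpha Confidence level for the Bartlett bounds.
#' @param override_s Optional user-fixed width in seconds.
#' @return An object of class `window_width_estimate` with
#'   `per_session_tcut`, `mean`, `sd`, `chosen_width`, `excluded`.
#' @export
estimate_window_width <- function(sessions, dt = 1, detrend_order = 1,
                                  max_lag_s = 300, alpha = 0.05,
                                  override_s = NULL) {
  if (inherits(sessions, "run_session")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1)
  tcuts <- numeric(0)
  excluded <- character(0)
  for (s in sessions) {
    hr <- resample_uniform(s$channels$hr, dt = dt)
    det <- detrend_poly(hr, detrend_order)
    gate <- adf_test(det)
    if (!gate$stationary) {
      det <- detrend_poly(hr, 2)
      gate <- adf_test(det)
    }
    if (!gate$stationary) {
      warning("session '", s$session_id,
              "' failed the stationarity gate; excluded")
      excluded <- c(excluded, s$session_id)
      next
    }
    ar <- acf_bartlett(det, max_lag_s = max_lag_s, alpha = alpha)
    tcuts <- c(tcuts, cutoff_lag(ar))
  }
  if (!length(tcuts))
    stop("all sessions failed the stationarity gate")
  m <- mean(tcuts)
  sdev <- if (length(tcuts) > 1) stats::sd(tcuts) else 0
  chosen <- if (!is.null(override_s)) {
    message("window width overridden to ", override_s, " s")
    override_s
  } else if (abs(m - 90) <= sdev) 90 else max(10, round(m / 10) * 10)
  structure(list(per_session_tcut = tcuts, mean = m, sd = sdev,
                 chosen_width = chosen, excluded = excluded),
            class = "window_width_estimate")
}

#' @export
print.window_width_estimate <- function(x, ...) {
  cat(sprintf("<window_width_estimate: t_cut = (%.1f +/- %.1f) s over %d sessions; chosen width %g s>\n",
              x$mean, x$sd, length(x$per_session_tcut), x$chosen_width))
  invisible(x)
}
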
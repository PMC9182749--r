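test_that("polynomial detrending removes fitted components", {
  lin <- uniform_series(3 + 0.5 * (0:99))
  expect_lt(max(abs(detrend_poly(lin, 1)$values)), 1e-9)
  expect_lt(max(abs(detrend_poly(uniform_series(rep(7, 50)), 2)$values)),
            1e-9)

  # detrending is linear: the residual of (line + sine) equals the residual
  # of the sine alone, and retains the oscillatory component
  tt <- 0:1999
  sine <- sin(2 * pi * tt / 40)
  mix <- uniform_series(2 + 0.01 * tt + sine)
  res <- detrend_poly(mix, 1)
  res_sine <- detrend_poly(uniform_series(sine), 1)
  expect_lt(max(abs(res$values - res_sine$values)), 1e-9)
  expect_gt(cor(res$values, sine), 0.999)
  expect_lt(abs(mean(res$values)), 1e-10)
})

test_that("Dickey-Fuller gate separates stationary noise from random walks", {
  ok <- 0; rw_flagged <- 0
  for (s in 1:100) {
    set.seed(s)
    if (adf_test(uniform_series(rnorm(500)))$stationary) ok <- ok + 1
    set.seed(1000 + s)
    if (!adf_test(uniform_series(cumsum(rnorm(500))))$stationary)
      rw_flagged <- rw_flagged + 1
  }
  expect_gte(ok, 95)
  expect_gte(rw_flagged, 90)

  # constant series: documented degenerate behaviour
  const <- adf_test(uniform_series(rep(5, 50)))
  expect_true(const$stationary)
  expect_identical(const$statistic, -Inf)

  # detrended ramp plus tiny noise is stationary by construction
  set.seed(9)
  ramp <- uniform_series(0.2 * (0:499) + rnorm(500, 0, 0.01))
  expect_true(adf_test(detrend_poly(ramp, 1))$stationary)
})

test_that("sample ACF with Bartlett bounds matches theory", {
  set.seed(21)
  iid <- uniform_series(rnorm(1000))
  ar <- acf_bartlett(iid, max_lag_s = 50)
  expect_equal(ar$acf[1], 1)
  expect_equal(ar$ci_upper[2], qnorm(0.975) / sqrt(1000), tolerance = 1e-12)
  expect_true(all(abs(ar$acf) <= 1))
  expect_equal(ar$ci_lower[-1], -ar$ci_upper[-1])

  # AR(1) phi = 0.9: lag-1 autocorrelation near phi
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    x <- as.numeric(stats::filter(rnorm(5600, 0, sqrt(1 - 0.81)), 0.9,
                                  method = "recursive"))[601:5600]
    r1 <- acf_bartlett(uniform_series(x), max_lag_s = 5)$acf[2]
    if (r1 > 0.88 && r1 < 0.92) hits <- hits + 1
  }
  expect_gte(hits, 90)

  expect_error(acf_bartlett(uniform_series(rnorm(50)), max_lag_s = 60),
               "max_lag")
})

test_that("ACF is time-reversal symmetric and scale invariant", {
  set.seed(5)
  x <- rnorm(400) + sin((1:400) / 10)
  a1 <- acf_bartlett(uniform_series(x), 50)
  a2 <- acf_bartlett(uniform_series(rev(x)), 50)
  expect_equal(a1$acf, a2$acf, tolerance = 1e-12)
  a3 <- acf_bartlett(uniform_series(3.7 * x - 12), 50)
  expect_equal(cutoff_lag(a1), cutoff_lag(a3), tolerance = 1e-12)
})

test_that("cutoff lag interpolates the bound crossing", {
  mk <- function(acf, bound) {
    structure(list(dt = 1, lags = seq_along(acf) - 1, acf = acf,
                   ci_upper = c(NA, rep(bound, length(acf) - 1)),
                   ci_lower = c(NA, rep(-bound, length(acf) - 1)),
                   alpha = 0.05, n = 1000, t_cut = NA_real_),
              class = "acf_result")
  }
  # crossing between lags 2 and 3: 2 + (0.2 - 0.062)/(0.2 - 0.05)
  expect_equal(cutoff_lag(mk(c(1, 0.5, 0.2, 0.05), 0.062)),
               2 + (0.2 - 0.062) / (0.2 - 0.05), tolerance = 1e-12)
  # already below at lag 1 -> one sampling step
  expect_equal(cutoff_lag(mk(c(1, 0.01, 0.0), 0.062)), 1)
  expect_error(cutoff_lag(mk(c(1, 0.9, 0.8), 0.062)), "never crosses")

  # persistent AR(1) yields a large cutoff; cutoff grows with persistence
  wins <- 0
  for (s in 1:20) {
    set.seed(s)
    mk_ar <- function(phi, n) {
      x <- as.numeric(stats::filter(rnorm(n + 500, 0, sqrt(1 - phi^2)), phi,
                                    method = "recursive"))[-(1:500)]
      uniform_series(x)
    }
    t_hi <- cutoff_lag(acf_bartlett(mk_ar(0.95, 2000), 600))
    t_lo <- cutoff_lag(acf_bartlett(mk_ar(0.6, 2000), 600))
    if (t_hi >= t_lo) wins <- wins + 1
    if (s <= 5) {
      t_cut99 <- cutoff_lag(acf_bartlett(mk_ar(0.99, 2000), 1200))
      expect_gt(t_cut99, 10)
    }
  }
  expect_gte(wins, 19)
})

test_that("window-width aggregation and override behave", {
  plan <- synthetic_plan(
    segments = list(regime_segment(0, 2000, "+/+", 1e-4, 1e-4)),
    duration = 2000, seed = 3, outlier_rate = 0)
  s <- generate_session(plan)$session
  est1 <- estimate_window_width(list(s), max_lag_s = 600)
  expect_equal(est1$sd, 0)
  expect_length(est1$per_session_tcut, 1)
  expect_equal(est1$mean, est1$per_session_tcut[1])

  expect_message(
    est2 <- estimate_window_width(list(s), override_s = 90),
    "overridden")
  expect_equal(est2$chosen_width, 90)
})
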
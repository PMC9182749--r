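# Synthetic wearable running sessions with known ground truth.  Sessions are
# built from contiguous regime segments; within each segment the external
# energy proxy and the deterministic heart rate ramp with slopes whose signs
# realize the planted regime (sign Delta E / sign Delta HR).  Channels are
# sampled at non-uniform intervals matching wearable acquisition statistics,
# AR(1) noise gives the heart rate a controllable correlation time, and
# sensor spikes/GPS noise exercise the cleaning chain.

#' Planted regime segment
#'
#' @param start Segment start in seconds.
#' @param duration Segment duration in seconds (>= the analysis window).
#' @param regime Sign pair `"+/+"`, `"+/-"`, `"-/+"` or `"-/-"`, read as
#'   sign(Delta E)/sign(Delta HR).
#' @param e_slope Energy-proxy slope in J/kg per s; its sign must match the
#'   regime's first sign.
#' @param hr_slope Heart-rate slope in bpm/s; sign must match the second.
#' @return A list of class `regime_segment`.
#' @export
regime_segment <- function(start, duration, regime, e_slope, hr_slope) {
  regime <- match.arg(regime, SIGN_LABELS)
  signs <- strsplit(regime, "/", fixed = TRUE)[[1L]]
  if ((signs[1] == "+") != (e_slope > 0))
    stop("e_slope sign does not match regime ", regime)
  if ((signs[2] == "+") != (hr_slope > 0))
    stop("hr_slope sign does not match regime ", regime)
  stopifnot(duration > 0)
  structure(list(start = start, duration = duration, regime = regime,
                 e_slope = e_slope, hr_slope = hr_slope),
            class = "regime_segment")
}

#' Build a contiguous segment list from a regime multiset
#'
#' Channels are realized as continuous piecewise-linear ramps (no resets at
#' boundaries): per channel the up/down slope magnitudes are balanced
#' against the planted sign mixture so the session never drifts downward
#' (heart rate must stay above the intense-zone floor and kinetic energy
#' positive), and segments are ordered greedily to bound the running
#' excursions while avoiding adjacent segments that flip both signs at
#' once.
#'
#' @param duration Session length in seconds.
#' @param segment_s Segment duration in seconds when `durations` is NULL.
#' @param e_slope,hr_slope Base slope magnitudes (energy proxy in J/kg/s,
#'   heart rate in bpm/s).
#' @param regimes Character vector of regime labels, one per segment;
#'   default cycles through the four regimes.
#' @param durations Optional per-segment durations in seconds (aligned with
#'   `regimes`), e.g. to realize exact regime time shares.
#' @param order_seed Seed for the randomized tie-breaks of the ordering.
#' @return List of [regime_segment()]s covering `[0, duration)`.
#' @export
default_segments <- function(duration = 3600, segment_s = 240,
                             e_slope = 0.2, hr_slope = 0.04,
                             regimes = NULL, durations = NULL,
                             order_seed = NULL) {
  n_seg <- if (is.null(regimes)) floor(duration / segment_s)
           else length(regimes)
  if (is.null(regimes))
    regimes <- rep(c("+/+", "-/-", "-/+", "+/-"), length.out = n_seg)
  if (is.null(durations)) durations <- rep(segment_s, n_seg)
  stopifnot(length(durations) == n_seg, all(durations > 0))
  e_sign <- ifelse(substr(regimes, 1, 1) == "+", 1, -1)
  h_sign <- ifelse(substr(regimes, 3, 3) == "+", 1, -1)
  # Channels face one-sided floors (heart-rate zone threshold, positive
  # kinetic energy), so down slopes are never enlarged: when down time
  # dominates, the up side is scaled to cancel the net drift; a majority of
  # up time is left to drift upward harmlessly.
  balance <- function(sgn, mag) {
    tp <- sum(durations[sgn > 0]); tm <- sum(durations[sgn < 0])
    if (tp == 0 || tm == 0) return(mag * sgn)  # one-sided plan: no balance
    ifelse(sgn > 0, mag * max(1, tm / tp), -mag)
  }
  e_sl <- balance(e_sign, e_slope)
  h_sl <- balance(h_sign, hr_slope)
  ord <- if (length(unique(regimes)) > 1)
    .order_bounded(e_sl * durations, h_sl * durations,
                   e_sign, h_sign, order_seed)
  else seq_along(regimes)
  starts <- cumsum(c(0, durations[ord]))[seq_len(n_seg)]
  lapply(seq_len(n_seg), function(i) {
    j <- ord[i]
    regime_segment(start = starts[i], duration = durations[j],
                   regime = regimes[j], e_slope = e_sl[j],
                   hr_slope = h_sl[j])
  })
}

# Greedy ordering of segments minimizing the running per-channel excursion
# (normalized by the largest step) while avoiding transitions that flip
# both signs at once -- windows straddling a single-sign flip remain
# attributable to one of the two adjacent regimes, double flips do not.
# Ties broken randomly (seeded).
.order_bounded <- function(e_step, h_step, e_sign, h_sign, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(e_step)
  se <- max(abs(e_step)); sh <- max(abs(h_step))
  remaining <- seq_len(n)
  out <- integer(n)
  e_sum <- 0; h_sum <- 0
  prev <- 0L
  for (i in seq_len(n)) {
    e_next <- e_sum + e_step[remaining]
    h_next <- h_sum + h_step[remaining]
    cost <- (abs(e_next) / se)^2 + (abs(h_next) / sh)^2 +
      100 * (e_next < -2 * se) + 100 * (h_next < -1.05 * sh)
    if (prev > 0L)
      cost <- cost + 2 * ((e_sign[remaining] != e_sign[prev]) &
                          (h_sign[remaining] != h_sign[prev]))
    best <- remaining[cost <= min(cost) + 1e-12]
    pick <- if (length(best) > 1) sample(best, 1L) else best
    out[i] <- pick
    e_sum <- e_sum + e_step[pick]; h_sum <- h_sum + h_step[pick]
    prev <- pick
    remaining <- setdiff(remaining, pick)
  }
  out
}

#' Synthetic session plan
#'
#' Defaults emulate an hour-long city run on a wrist device: 240 s regime
#' segments cycling through the four regimes, heart rate around 162 bpm with
#' AR(1) noise of 85 s correlation time, wearable sampling-interval
#' statistics of (5.1 +/- 2.6) s for HR, (2.6 +/- 1.4) s for speed and
#' (2.0 +/- 1.8) s for altitude, and occasional sensor spikes.
#'
#' @param segments List of [regime_segment()]s (contiguous, non-overlapping);
#'   default: a cycle of the four regimes covering `duration`.
#' @param duration Session length in seconds.
#' @param hr_baseline Baseline heart rate in bpm.
#' @param hr_noise_sd Marginal SD of the AR(1) heart-rate noise in bpm.
#' @param ar1_tau AR(1) correlation time in seconds (phi = exp(-dt / tau)).
#' @param speed_baseline Baseline speed in m/s.
#' @param kinetic_share Fraction of the energy slope realized by the kinetic
#'   term (the rest goes to altitude).
#' @param speed_noise_sd GPS speed noise SD in m/s.
#' @param altitude_noise_sd Altitude noise SD in m.
#' @param sampling Named list of `c(mean, sd)` sampling intervals per
#'   channel in seconds.
#' @param outlier_rate Per-sample probability of a sensor spike on HR.
#' @param fatigue_gain Reserved dial for rising-regularity sessions
#'   (see [generate_fatigue_series()]); 0 disables it.
#' @param age,vo2max,session_id,date Session metadata.
#' @param seed RNG seed.
#' @return A list of class `synthetic_plan`.
#' @export
synthetic_plan <- function(segments = NULL, duration = 3600,
                           hr_baseline = 166, hr_noise_sd = 1.2,
                           ar1_tau = 85, speed_baseline = 2.6,
                           kinetic_share = 0.03, speed_noise_sd = 0.15,
                           altitude_noise_sd = 0.3,
                           sampling = list(hr = c(5.1, 2.6),
                                           speed = c(2.6, 1.4),
                                           altitude = c(2.0, 1.8)),
                           outlier_rate = 0.002, fatigue_gain = 0,
                           age = 57, vo2max = 36,
                           session_id = "synthetic", date = "2021-06-18",
                           seed = 1L) {
  if (is.null(segments)) segments <- default_segments(duration)
  starts <- vapply(segments, `[[`, numeric(1), "start")
  durs <- vapply(segments, `[[`, numeric(1), "duration")
  o <- order(starts)
  segments <- segments[o]; starts <- starts[o]; durs <- durs[o]
  if (length(segments) > 1 &&
      any(abs(starts[-1] - (starts + durs)[-length(starts)]) > 1e-9))
    stop("segments must be contiguous and non-overlapping")
  stopifnot(hr_noise_sd >= 0, ar1_tau > 0, kinetic_share >= 0,
            kinetic_share <= 1, outlier_rate >= 0, outlier_rate <= 1)
  structure(list(segments = segments, duration = duration,
                 hr_baseline = hr_baseline, hr_noise_sd = hr_noise_sd,
                 ar1_tau = ar1_tau, speed_baseline = speed_baseline,
                 kinetic_share = kinetic_share,
                 speed_noise_sd = speed_noise_sd,
                 altitude_noise_sd = altitude_noise_sd,
                 sampling = sampling, outlier_rate = outlier_rate,
                 fatigue_gain = fatigue_gain, age = age, vo2max = vo2max,
                 session_id = session_id, date = date, seed = seed),
            class = "synthetic_plan")
}

#' @export
print.synthetic_plan <- function(x, ...) {
  cat(sprintf("<synthetic_plan '%s': %d segments over %g s, seed %d>\n",
              x$session_id, length(x$segments), x$duration, x$seed))
  invisible(x)
}

# Continuous piecewise-linear ramp on the 1 s grid: slopes integrate across
# segment boundaries with no resets, starting from 0; the value is held
# beyond the last segment.
.segment_ramp <- function(tt, segments, slope_of) {
  slope_at <- numeric(length(tt))
  for (seg in segments) {
    inside <- tt >= seg$start & tt < seg$start + seg$duration
    slope_at[inside] <- slope_of(seg)
  }
  dt <- diff(tt)
  c(0, cumsum(slope_at[-length(tt)] * dt))
}

# Truncated-Gaussian sampling times over [0, duration].  Censoring at the
# lower bound shifts the interval moments (strongly so for the altitude
# channel, whose nominal mean is close to the bound), so the underlying
# Gaussian parameters are moment-matched numerically to make the realized
# mean/SD agree with the plan.
.sample_times <- function(duration, mean_sd, lower = 0.5) {
  par <- .censored_normal_params(mean_sd[1], mean_sd[2], lower)
  n_guess <- ceiling(duration / max(mean_sd[1], lower) * 2) + 20
  gaps <- pmax(stats::rnorm(n_guess, par[1], par[2]), lower)
  ts <- cumsum(c(0, gaps))
  ts[ts <= duration]
}

# Underlying (mu, sigma) such that max(N(mu, sigma), c) has the target mean
# and SD; falls back to the naive parameters when censoring is negligible.
.censored_normal_params <- function(m, s, c) {
  if (s <= 0) return(c(m, max(s, 0)))
  if (stats::pnorm(c, m, s) < 1e-4) return(c(m, s))
  moments <- function(p) {
    mu <- p[1]; sg <- exp(p[2])
    a <- (c - mu) / sg
    Phi <- stats::pnorm(a); phi <- stats::dnorm(a)
    lam <- phi / max(1 - Phi, 1e-12)
    m1_t <- mu + sg * lam                       # E[Y | Y > c]
    v_t <- sg^2 * (1 + a * lam - lam^2)         # Var[Y | Y > c]
    m1 <- Phi * c + (1 - Phi) * m1_t
    m2 <- Phi * c^2 + (1 - Phi) * (v_t + m1_t^2)
    c(m1, sqrt(max(m2 - m1^2, 0)))
  }
  obj <- function(p) sum((moments(p) - c(m, s))^2)
  fit <- stats::optim(c(m, log(s)), obj)
  c(fit$par[1], exp(fit$par[2]))
}

#' Generate a synthetic session from a plan
#'
#' @param plan A [synthetic_plan()].
#' @return List with `session` (a [run_session()]), `plan`, and `truth_1hz`
#'   (data.frame `t_s`, `regime` giving the planted regime on the 1 s grid,
#'   `NA` outside segments).
#' @export
generate_session <- function(plan) {
  stopifnot(inherits(plan, "synthetic_plan"))
  if (!is.null(plan$seed)) set.seed(plan$seed)
  tt <- 0:plan$duration
  g <- 9.80665

  hr_det <- plan$hr_baseline +
    .segment_ramp(tt, plan$segments, function(s) s$hr_slope)
  phi <- exp(-1 / plan$ar1_tau)
  eps_sd <- plan$hr_noise_sd * sqrt(1 - phi^2)
  noise <- as.numeric(stats::filter(stats::rnorm(length(tt), 0, eps_sd),
                                    phi, method = "recursive"))
  hr_true <- hr_det + noise

  k_dev <- .segment_ramp(tt, plan$segments,
                         function(s) s$e_slope * plan$kinetic_share)
  p_dev <- .segment_ramp(tt, plan$segments,
                         function(s) s$e_slope * (1 - plan$kinetic_share))
  K <- plan$speed_baseline^2 / 2 + k_dev
  if (any(K <= 0))
    stop("infeasible plan: kinetic ramp forces non-positive speed")
  v_true <- sqrt(2 * K)
  z_true <- 100 + p_dev / g

  if (any(hr_true < 30 | hr_true > 220))
    stop("infeasible plan: heart rate leaves the physiological range")

  sample_channel <- function(name, underlying, noise_sd, clamp0 = FALSE) {
    ts <- .sample_times(plan$duration, plan$sampling[[name]])
    vals <- stats::approx(tt, underlying, xout = ts)$y
    if (noise_sd > 0) vals <- vals + stats::rnorm(length(ts), 0, noise_sd)
    if (clamp0) vals <- pmax(vals, 0)
    raw_channel(name, ts, vals)
  }
  hr_ch <- sample_channel("hr", hr_true, 0)
  if (plan$outlier_rate > 0) {
    spike <- stats::runif(length(hr_ch$values)) < plan$outlier_rate
    if (any(spike)) {
      s <- stats::sd(hr_ch$values)
      mag <- stats::runif(sum(spike), 5, 10) * s *
        sample(c(-1, 1), sum(spike), replace = TRUE)
      hr_ch$values[spike] <- hr_ch$values[spike] + mag
    }
  }
  speed_ch <- sample_channel("speed", v_true, plan$speed_noise_sd,
                             clamp0 = TRUE)
  alt_ch <- sample_channel("altitude", z_true, plan$altitude_noise_sd)

  session <- run_session(plan$session_id, plan$date, plan$age,
                         list(hr_ch, speed_ch, alt_ch),
                         vo2max = plan$vo2max, duration = plan$duration)
  regime <- rep(NA_character_, length(tt))
  for (seg in plan$segments) {
    inside <- tt >= seg$start & tt < seg$start + seg$duration
    regime[inside] <- seg$regime
  }
  list(session = session, plan = plan,
       truth_1hz = data.frame(t_s = tt, regime = regime))
}

#' Ground-truth labels for sliding windows
#'
#' A window is labelled iff `[start, start + width)` lies entirely inside
#' one planted segment.
#'
#' @param plan A [synthetic_plan()].
#' @param width_s Window width in seconds.
#' @return Data.frame `window_start_s`, `regime`.
#' @export
ground_truth_labels <- function(plan, width_s = 90) {
  rows <- lapply(plan$segments, function(seg) {
    if (seg$duration < width_s) return(NULL)
    lo <- ceiling(seg$start - 1e-9)
    hi <- floor(seg$start + seg$duration - width_s + 1e-9)
    if (hi < lo) return(NULL)
    data.frame(window_start_s = lo:hi, regime = seg$regime)
  })
  do.call(rbind, rows)
}

#' Generate a cohort of sessions with a planted VO2max/regime trend
#'
#' VO2max rises linearly across sessions while the planted share of the
#' `-/+` regime rises and the `-/-` share falls (the remainder is split
#' evenly between `+/+` and `+/-`), emulating a fitness-improvement cohort.
#'
#' @param n_sessions Number of sessions (>= 3).
#' @param vo2max_range Length-2 numeric: VO2max of the first and last
#'   session in mL/kg/min.
#' @param mp_share_range Planted `-/+` share, first to last session.
#' @param mm_share_range Planted `-/-` share, first to last session.
#' @param duration,segment_s Session length and segment duration in seconds.
#' @param seed Base RNG seed (per-session seeds are derived from it).
#' @param ... Further arguments passed to [synthetic_plan()].
#' @return List with `sessions` (list of [run_session()]), `plans`,
#'   `expected_shares` (data.frame of planted per-session regime shares --
#'   both the continuous trend and the realized integer segment counts --
#'   and vo2max).
#' @export
generate_cohort <- function(n_sessions = 12, vo2max_range = c(32, 38),
                            mp_share_range = c(0.16, 0.32),
                            mm_share_range = c(0.29, 0.19),
                            duration = 3600, segment_s = 180, seed = 1L,
                            ...) {
  stopifnot(n_sessions >= 3)
  f <- if (n_sessions == 1) 0 else (seq_len(n_sessions) - 1) / (n_sessions - 1)
  vo2 <- vo2max_range[1] + f * diff(vo2max_range)
  mp <- mp_share_range[1] + f * diff(mp_share_range)
  mm <- mm_share_range[1] + f * diff(mm_share_range)
  rest <- 1 - mp - mm
  if (any(rest < 0)) stop("trend produces negative +/+ and +/- shares")
  n_seg <- floor(duration / segment_s)
  share_mat <- cbind("+/+" = rest / 2, "+/-" = rest / 2,
                     "-/+" = mp, "-/-" = mm)
  count_mat <- allocate_counts(share_mat, n_seg)
  sessions <- vector("list", n_sessions)
  plans <- vector("list", n_sessions)
  for (i in seq_len(n_sessions)) {
    counts <- count_mat[i, ]
    regimes <- rep(colnames(count_mat), counts)
    # per-regime durations realize the planned time shares exactly, so the
    # planted frequencies are not quantized by the integer segment counts
    per_seg <- share_mat[i, ] * duration / pmax(counts, 1L)
    durations <- rep(per_seg, counts)
    plan <- synthetic_plan(
      segments = default_segments(duration, regimes = regimes,
                                  durations = durations,
                                  order_seed = seed + 1000L * i),
      duration = duration, vo2max = vo2[i],
      session_id = sprintf("cohort-%02d", i),
      date = format(as.Date("2020-12-24") + 30 * (i - 1)),
      seed = seed + 1000L * i + 1L, ...)
    sessions[[i]] <- generate_session(plan)$session
    plans[[i]] <- plan
  }
  expected <- data.frame(session_id = vapply(plans, `[[`, character(1),
                                             "session_id"),
                         vo2max = vo2, share_pp = rest / 2,
                         share_pm = rest / 2, share_mp = mp, share_mm = mm,
                         count_pp = count_mat[, "+/+"],
                         count_pm = count_mat[, "+/-"],
                         count_mp = count_mat[, "-/+"],
                         count_mm = count_mat[, "-/-"],
                         n_seg = n_seg)
  list(sessions = sessions, plans = plans, expected_shares = expected)
}

# Integer segment counts per session (rows) and regime (columns) that track
# each regime's planned share trajectory faithfully: per regime, counts are
# increments of the rounded cumulative allocation (so each column's running
# total never drifts more than half a segment from plan), then row totals
# are repaired to n_seg by moving single segments to/from the regimes with
# the largest rounding residuals.
allocate_counts <- function(share_mat, n_seg) {
  planned <- share_mat * n_seg
  cum <- apply(planned, 2, cumsum)
  alloc <- apply(round(cum), 2, function(p) diff(c(0, p)))
  alloc <- matrix(alloc, nrow = nrow(share_mat),
                  dimnames = dimnames(share_mat))
  for (i in seq_len(nrow(alloc))) {
    resid <- planned[i, ] - alloc[i, ]
    while (sum(alloc[i, ]) < n_seg) {
      j <- which.max(resid)
      alloc[i, j] <- alloc[i, j] + 1
      resid[j] <- resid[j] - 1
    }
    while (sum(alloc[i, ]) > n_seg) {
      j <- which.min(ifelse(alloc[i, ] > 0, resid, Inf))
      alloc[i, j] <- alloc[i, j] - 1
      resid[j] <- resid[j] + 1
    }
  }
  storage.mode(alloc) <- "integer"
  alloc
}

#' HR-like series with rising regularity (fatigue analogue)
#'
#' The share of variance carried by a deterministic oscillation grows
#' linearly with normalized time at rate `fatigue_gain` while the white
#' noise share shrinks correspondingly, so determinism (DET) rises from the
#' start to the end of the series; `fatigue_gain = 0` gives a flat profile.
#'
#' @param duration Length in seconds (>= 3 analysis windows).
#' @param fatigue_gain Increase of the deterministic variance share over the
#'   whole session, in `[0, 1]`.
#' @param seed RNG seed.
#' @param baseline Baseline level in bpm.
#' @param amplitude Total fluctuation SD in bpm.
#' @param period Oscillation period in seconds.
#' @param w0 Deterministic variance share at the start, in `[0, 1)`.
#' @return A [uniform_series()] at 1 Hz.
#' @export
generate_fatigue_series <- function(duration = 600, fatigue_gain = 0.6,
                                    seed = 1L, baseline = 160,
                                    amplitude = 3, period = 25, w0 = 0.15) {
  if (!is.numeric(fatigue_gain) || fatigue_gain < 0 || fatigue_gain > 1)
    stop("'fatigue_gain' must be in [0, 1]")
  stopifnot(duration >= 270, w0 >= 0, w0 < 1)
  set.seed(seed)
  tt <- 0:duration
  w <- pmin(w0 + fatigue_gain * tt / duration, 0.98)
  # random phase: section edges otherwise sit at fixed partial cycles,
  # which would bias section-wise DET identically for every seed
  osc <- sqrt(2) * sin(2 * pi * tt / period + stats::runif(1, 0, 2 * pi))
  x <- baseline + amplitude * (sqrt(w) * osc +
                               sqrt(1 - w) * stats::rnorm(length(tt)))
  uniform_series(x, t0 = 0, dt = 1)
}
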
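# Data cleaning: maximal-effort zone restriction via the Tanaka age-predicted
# maximum heart rate, z-score despiking, zero-phase Butterworth smoothing of
# the GPS speed, altitude rebasing.

#' Cleaning configuration
#'
#' @param hr_zone_fraction Fraction of HRmax delimiting the intense zone
#'   (default 0.9: analysis keeps HR above 90% of HRmax).
#' @param zscore_threshold Outlier threshold in SD units (default 3).
#' @param butter_cutoff Normalized Butterworth cutoff as a fraction of the
#'   Nyquist frequency (default 0.01, i.e. 0.005 Hz on a 1 Hz grid).
#' @param butter_order Butterworth filter order (default 2).
#' @param min_segment_s Shortest retained intense-zone segment in seconds.
#' @param max_gap_s Largest sampling gap interpolated across, in seconds.
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(hr_zone_fraction = 0.9, zscore_threshold = 3,
                            butter_cutoff = 0.01, butter_order = 2,
                            min_segment_s = 90, max_gap_s = 30) {
  stopifnot(hr_zone_fraction > 0, hr_zone_fraction <= 1,
            zscore_threshold > 0,
            butter_cutoff > 0, butter_cutoff < 1,
            butter_order >= 1, min_segment_s >= 0, max_gap_s > 0)
  structure(list(hr_zone_fraction = hr_zone_fraction,
                 zscore_threshold = zscore_threshold,
                 butter_cutoff = butter_cutoff,
                 butter_order = butter_order,
                 min_segment_s = min_segment_s,
                 max_gap_s = max_gap_s),
            class = "cleaning_config")
}

#' Tanaka age-predicted maximum heart rate
#'
#' `HRmax = 208 - 0.7 * age`.
#'
#' @param age Age in years, in (0, 130).
#' @return Predicted maximum heart rate in bpm.
#' @export
hr_max_tanaka <- function(age) {
  if (!is.numeric(age) || any(!is.finite(age)) || any(age <= 0) ||
      any(age >= 130))
    stop("'age' must be in (0, 130) years")
  208 - 0.7 * age
}

#' Restrict a heart-rate series to the intense-effort zone
#'
#' Marks samples with `hr >= fraction * hrmax` and returns the contiguous
#' retained segments longer than `min_segment_s`.  Downstream windows must lie
#' entirely within one retained segment.
#'
#' @param hr A [uniform_series()] of heart rate in bpm.
#' @param hrmax Maximum heart rate in bpm (e.g. from [hr_max_tanaka()]).
#' @param fraction Zone threshold as a fraction of `hrmax` (default 0.9).
#' @param min_segment_s Shortest retained segment in seconds.
#' @return List with `mask` (logical per sample), `threshold` (bpm) and
#'   `segments`, a data.frame with columns `start_idx`, `end_idx`,
#'   `start_s`, `end_s` (1-based sample indices, inclusive).
#' @export
restrict_to_intense_zone <- function(hr, hrmax, fraction = 0.9,
                                     min_segment_s = 90) {
  stopifnot(inherits(hr, "uniform_series"), hrmax > 0,
            fraction > 0, fraction <= 1)
  thr <- fraction * hrmax
  mask <- hr$values >= thr
  segs <- mask_segments(mask, min_len = ceiling(min_segment_s / hr$dt))
  if (!nrow(segs))
    warning("no samples above ", signif(thr, 6),
            " bpm: no intense-zone segments retained")
  tt <- series_time(hr)
  segs$start_s <- if (nrow(segs)) tt[segs$start_idx] else numeric(0)
  segs$end_s <- if (nrow(segs)) tt[segs$end_idx] else numeric(0)
  list(mask = mask, threshold = thr, segments = segs)
}

# Contiguous TRUE runs of at least min_len samples.
mask_segments <- function(mask, min_len = 1L) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start_idx = starts[keep], end_idx = ends[keep])
}

#' Remove z-score outliers from a series
#'
#' Samples with `|x - mean| / sd > threshold` (mean and SD over the full
#' series) are replaced by linear interpolation from the neighbouring
#' inliers, preserving the sampling grid.  Despiking is applied to the raw
#' channel *before* grid alignment: interpolating first would smear a
#' single-sample sensor spike across several grid points.
#'
#' @param series A [uniform_series()] or [raw_channel()] with at least 3
#'   samples.
#' @param threshold Outlier threshold in SD units (default 3).
#' @return An object of the same class and length as the input.
#' @export
remove_outliers_zscore <- function(series, threshold = 3) {
  stopifnot(inherits(series, c("uniform_series", "raw_channel")),
            threshold > 0)
  x <- series$values
  if (length(x) < 3L) stop("need >= 3 samples")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(series)
  out <- abs(x - mean(x)) / s > threshold
  if (!any(out) || all(out)) return(series)
  tt <- if (inherits(series, "raw_channel")) series$timestamps
        else series$t0 + (seq_along(x) - 1) * series$dt
  x[out] <- stats::approx(tt[!out], x[!out], xout = tt[out],
                          method = "linear", rule = 2)$y
  if (inherits(series, "raw_channel"))
    raw_channel(series$name, series$timestamps, x)
  else uniform_series(x, t0 = series$t0, dt = series$dt)
}

#' Zero-phase Butterworth low-pass filter for speed
#'
#' Forward-backward (zero-phase) filtering so the smoothed speed is not
#' time-shifted relative to heart rate; DC gain is exactly 1.
#'
#' @param speed A [uniform_series()] of speed in m/s.
#' @param cutoff Normalized cutoff as a fraction of Nyquist (default 0.01).
#' @param order Filter order (default 2; zero-phase application doubles the
#'   effective roll-off).
#' @return A filtered [uniform_series()] of the same length.
#' @export
lowpass_speed <- function(speed, cutoff = 0.01, order = 2) {
  stopifnot(inherits(speed, "uniform_series"),
            cutoff > 0, cutoff < 1, order >= 1)
  n <- length(speed$values)
  if (n <= 3 * (order + 1))
    stop("series too short for order-", order, " zero-phase filtering")
  bf <- signal::butter(order, cutoff, type = "low")
  # odd-reflection padding suppresses the filter's startup/teardown
  # transients (the impulse response is ~1/cutoff samples long)
  # filter deviations from the mean so the DC component passes exactly
  mu <- mean(speed$values)
  x <- speed$values - mu
  pad <- min(n - 1, ceiling(3 / cutoff))
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y <- y[(pad + 1):(pad + n)] + mu
  uniform_series(as.numeric(y), t0 = speed$t0, dt = speed$dt)
}

#' Rebase an altitude series to its starting point
#'
#' Subtracts the first value so every session starts at altitude 0.
#'
#' @param z A non-empty [uniform_series()] of altitude in m.
#' @return A [uniform_series()] with first value 0.
#' @export
rebase_altitude <- function(z) {
  stopifnot(inherits(z, "uniform_series"))
  if (!length(z$values)) stop("empty altitude series")
  uniform_series(z$values - z$values[1L], t0 = z$t0, dt = z$dt)
}

#' Clean and align a session
#'
#' Applies the cleaning chain in order: z-score despiking on the raw HR
#' channel, channel alignment onto the uniform grid, speed low-pass
#' filtering, altitude rebasing, then intense-zone segmentation on the
#' cleaned HR.
#'
#' @param session A [run_session()] with hr, speed and altitude channels.
#' @param config A [cleaning_config()].
#' @param dt Grid step in seconds.
#' @return List with elements `hr`, `speed`, `altitude`
#'   ([uniform_series()] on a shared grid), `zone` (from
#'   [restrict_to_intense_zone()]), `hrmax` and `config`.
#' @export
clean_session <- function(session, config = cleaning_config(), dt = 1) {
  stopifnot(inherits(session, "run_session"))
  session$channels$hr <- remove_outliers_zscore(session$channels$hr,
                                                config$zscore_threshold)
  aligned <- align_session(session, dt = dt)
  hr <- aligned$hr
  speed <- if (!is.null(aligned$speed))
    lowpass_speed(aligned$speed, config$butter_cutoff, config$butter_order)
  altitude <- if (!is.null(aligned$altitude)) rebase_altitude(aligned$altitude)
  hrmax <- hr_max_tanaka(session$age)
  zone <- restrict_to_intense_zone(hr, hrmax,
                                   fraction = config$hr_zone_fraction,
                                   min_segment_s = config$min_segment_s)
  list(hr = hr, speed = speed, altitude = altitude, zone = zone,
       hrmax = hrmax, config = config)
}
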
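# Sliding-window trend features.  The external energy demand proxy E sums a
# potential term V = g * (z - z0) and a kinetic term K = v^2 / 2, each min-max
# normalized to [0, 1] over the cleaned session so that E ranges over [0, 2].
# Per window, Delta X = gamma0(X) + gamma1(X): a standardized level shift of
# the window mean relative to the window's first point plus the window
# skewness, both using the population SD.  The sign pair
# (sign Delta E, sign Delta HR) defines the heartbeat-dynamics regime.

#' External energy-demand proxy
#'
#' @param z Rebased altitude [uniform_series()] (first value 0), in m.
#' @param v Cleaned speed [uniform_series()] on the same grid, in m/s.
#' @param g Gravitational acceleration in m/s^2 (default 9.80665).
#' @return An object of class `energy_series` with fields `t0`, `dt`,
#'   `v_norm` (normalized potential term), `k_norm` (normalized kinetic
#'   term), `e = v_norm + k_norm` in `[0, 2]`, and `g`.  A degenerate
#'   (constant) term is normalized to all zeros with a warning.
#' @export
compute_energy <- function(z, v, g = 9.80665) {
  stopifnot(inherits(z, "uniform_series"), inherits(v, "uniform_series"))
  if (!same_grid(z, v)) stop("altitude and speed are not on the same grid")
  pot <- g * z$values
  kin <- v$values^2 / 2
  norm01 <- function(x, what) {
    rng <- range(x)
    if (diff(rng) == 0) {
      warning("constant ", what, " term: normalized to 0")
      return(rep(0, length(x)))
    }
    (x - rng[1]) / diff(rng)
  }
  v_norm <- norm01(pot, "potential")
  k_norm <- norm01(kin, "kinetic")
  structure(list(t0 = z$t0, dt = z$dt, v_norm = v_norm, k_norm = k_norm,
                 e = v_norm + k_norm, g = g),
            class = "energy_series")
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf("<energy_series: %d samples, dt = %g s, e in [%.3g, %.3g]>\n",
              length(x$e), x$dt, min(x$e), max(x$e)))
  invisible(x)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Standardized level shift of a window
#'
#' `gamma0 = (mean(x) - x[1]) / sd(x)` with the population SD; 0 when the
#' window is constant.
#'
#' @param x Numeric window values (length >= 3); the first element is the
#'   window's initial point.
#' @return Dimensionless level-shift statistic.
#' @export
gamma0 <- function(x) {
  if (length(x) < 3) stop("window too short (need >= 3 samples)")
  s <- pop_sd(x)
  if (s == 0) return(0)
  (mean(x) - x[1L]) / s
}

#' Window skewness
#'
#' Fisher-Pearson skewness `mean(((x - mean(x)) / sd(x))^3)` with the
#' population SD; 0 when the window is constant.
#'
#' @param x Numeric window values (length >= 3).
#' @return Dimensionless skewness.
#' @export
gamma1 <- function(x) {
  if (length(x) < 3) stop("window too short (need >= 3 samples)")
  s <- pop_sd(x)
  if (s == 0) return(0)
  mean(((x - mean(x)) / s)^3)
}

#' Sliding-window features Delta E and Delta HR
#'
#' One feature record per admissible window start: windows slide point by
#' point on the uniform grid, span `width_s` seconds (half-open, i.e.
#' `width_s / dt` samples), and must lie entirely inside one retained
#' segment.
#'
#' @param hr Heart-rate [uniform_series()].
#' @param energy An [compute_energy()] result on the same grid.
#' @param width_s Window width in seconds (default 90).
#' @param segments Optional data.frame with `start_idx`, `end_idx` columns
#'   (1-based, inclusive) restricting admissible windows, e.g. the
#'   intense-zone segments from [restrict_to_intense_zone()]; default uses
#'   the whole series.
#' @return A data.frame of class `window_features` with columns
#'   `window_start_s`, `width_s`, `delta_e`, `delta_hr`, `gamma0_e`,
#'   `gamma1_e`, `gamma0_hr`, `gamma1_hr`.
#' @export
window_features <- function(hr, energy, width_s = 90, segments = NULL) {
  stopifnot(inherits(hr, "uniform_series"), inherits(energy, "energy_series"))
  if (abs(hr$t0 - energy$t0) > 1e-9 || abs(hr$dt - energy$dt) > 1e-9 ||
      length(hr$values) != length(energy$e))
    stop("hr and energy are not on the same grid")
  w <- round(width_s / hr$dt)
  if (w < 3) stop("window shorter than 3 samples")
  n <- length(hr$values)
  if (is.null(segments))
    segments <- data.frame(start_idx = 1L, end_idx = n)
  starts <- integer(0)
  for (i in seq_len(nrow(segments))) {
    a <- segments$start_idx[i]; b <- segments$end_idx[i]
    if (b - a + 1L < w) {
      warning("segment of ", (b - a + 1L) * hr$dt,
              " s shorter than the ", width_s, " s window: skipped")
      next
    }
    starts <- c(starts, a:(b - w + 1L))
  }
  tt <- series_time(hr)
  rows <- lapply(starts, function(a) {
    idx <- a:(a + w - 1L)
    xh <- hr$values[idx]; xe <- energy$e[idx]
    g0h <- gamma0(xh); g1h <- gamma1(xh)
    g0e <- gamma0(xe); g1e <- gamma1(xe)
    c(tt[a], width_s, g0e + g1e, g0h + g1h, g0e, g1e, g0h, g1h)
  })
  out <- as.data.frame(do.call(rbind, c(rows, list(matrix(numeric(0), ncol = 8)))))
  names(out) <- c("window_start_s", "width_s", "delta_e", "delta_hr",
                  "gamma0_e", "gamma1_e", "gamma0_hr", "gamma1_hr")
  class(out) <- c("window_features", "data.frame")
  out
}

#' Write window features to CSV
#'
#' @param features A [window_features()] data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}
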
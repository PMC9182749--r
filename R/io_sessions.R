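# Session data model and canonical CSV I/O.
#
# A running session holds up to three raw channels (hr in bpm, speed in m/s,
# altitude in m) sampled at possibly non-uniform timestamps, plus subject
# metadata.  All downstream analysis works on 1 Hz uniform grids produced by
# resample_uniform().

CHANNEL_NAMES <- c("hr", "speed", "altitude")
CHANNEL_UNITS <- c(hr = "bpm", speed = "m/s", altitude = "m")

#' Raw (possibly non-uniform) channel of a running session
#'
#' @param name One of `"hr"`, `"speed"`, `"altitude"`.
#' @param timestamps Seconds since session start; non-negative, strictly
#'   increasing, same length as `values`.
#' @param values Channel values (bpm, m/s or m).
#' @return An object of class `raw_channel`.
#' @export
raw_channel <- function(name, timestamps, values) {
  name <- match.arg(name, CHANNEL_NAMES)
  timestamps <- as.numeric(timestamps)
  values <- as.numeric(values)
  if (length(timestamps) != length(values))
    stop("channel '", name, "': timestamps and values differ in length")
  if (length(timestamps) && any(timestamps < 0))
    stop("channel '", name, "': negative timestamps")
  if (length(timestamps) > 1L) {
    bad <- which(diff(timestamps) <= 0)
    if (length(bad))
      stop("channel '", name, "': non-monotonic timestamps at row ", bad[1L] + 1L)
  }
  if (name == "speed" && length(values) && any(values < 0))
    stop("channel 'speed': negative speed values")
  structure(list(name = name, timestamps = timestamps, values = values),
            class = "raw_channel")
}

#' @export
print.raw_channel <- function(x, ...) {
  cat(sprintf("<raw_channel %s [%s]: %d samples, t in [%g, %g] s>\n",
              x$name, CHANNEL_UNITS[[x$name]], length(x$values),
              if (length(x$timestamps)) min(x$timestamps) else NA,
              if (length(x$timestamps)) max(x$timestamps) else NA))
  invisible(x)
}

#' Running session: channels plus subject metadata
#'
#' @param session_id Identifier string.
#' @param date ISO date string (`"YYYY-MM-DD"`).
#' @param age Subject age in years (> 0).
#' @param channels Named list of [raw_channel()] objects; `hr` is required,
#'   at most one channel per name.
#' @param vo2max Device-estimated VO2max in mL/kg/min, or `NA` when absent.
#' @param duration Session duration in seconds; defaults to the largest
#'   timestamp over all channels.
#' @return An object of class `run_session`.
#' @export
run_session <- function(session_id, date, age, channels, vo2max = NA_real_,
                        duration = NULL) {
  if (!is.list(channels) || !length(channels))
    stop("'channels' must be a non-empty list of raw_channel objects")
  nms <- vapply(channels, function(ch) ch$name, character(1))
  if (anyDuplicated(nms))
    stop("duplicate channel: ", nms[duplicated(nms)][1L])
  names(channels) <- nms
  if (!"hr" %in% nms)
    stop("required channel 'hr' is missing")
  age <- as.numeric(age)
  if (!is.finite(age) || age <= 0)
    stop("'age' must be a positive number of years")
  tmax <- max(vapply(channels, function(ch) max(ch$timestamps, 0), numeric(1)))
  if (is.null(duration)) duration <- tmax
  if (duration < tmax)
    stop("'duration' must be at least the largest channel timestamp")
  structure(list(session_id = as.character(session_id),
                 date = as.character(date),
                 age = age,
                 vo2max = as.numeric(vo2max),
                 channels = channels,
                 duration = as.numeric(duration)),
            class = "run_session")
}

#' @export
print.run_session <- function(x, ...) {
  cat(sprintf("<run_session '%s' (%s): age %g, VO2max %s, %g s>\n",
              x$session_id, x$date, x$age,
              if (is.na(x$vo2max)) "NA" else format(x$vo2max), x$duration))
  for (ch in x$channels) print(ch)
  invisible(x)
}

#' Uniformly sampled series
#'
#' Values on the implied grid `t0 + (i - 1) * dt`, `i = 1..length(values)`.
#'
#' @param values Numeric vector without missing values.
#' @param t0 Start time in seconds.
#' @param dt Sampling step in seconds (> 0).
#' @return An object of class `uniform_series`.
#' @export
uniform_series <- function(values, t0 = 0, dt = 1) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("uniform series must not contain missing values")
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0")
  structure(list(t0 = as.numeric(t0), dt = as.numeric(dt), values = values),
            class = "uniform_series")
}

#' Timestamps of a uniform series
#' @param x A `uniform_series`.
#' @return Numeric vector of timestamps in seconds.
#' @export
series_time <- function(x) x$t0 + (seq_along(x$values) - 1) * x$dt

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series: %d samples, dt = %g s, t0 = %g s>\n",
              length(x$values), x$dt, x$t0))
  invisible(x)
}

#' @export
length.uniform_series <- function(x) length(x$values)

same_grid <- function(a, b, tol = 1e-9) {
  abs(a$t0 - b$t0) < tol && abs(a$dt - b$dt) < tol &&
    length(a$values) == length(b$values)
}

#' Read a session from the canonical long-format CSV
#'
#' The dialect is UTF-8 CSV with header `channel,t_s,value`, preceded by
#' metadata comment lines of the form `# key=value` (keys: `session_id`,
#' `date`, `age`, `vo2max`; `vo2max` may be empty).
#'
#' @param path Path to a CSV file written by [write_session_csv()] (or by
#'   hand in the same dialect).
#' @return A [run_session()].
#' @export
read_session_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  for (key in c("session_id", "date", "age"))
    if (is.null(meta[[key]]))
      stop("metadata line '# ", key, "=...' missing in ", path)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  if (!identical(names(df), c("channel", "t_s", "value")))
    stop("expected CSV header 'channel,t_s,value' in ", path)
  unknown <- setdiff(unique(df$channel), CHANNEL_NAMES)
  if (length(unknown))
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "))
  channels <- lapply(split(df, factor(df$channel, levels = CHANNEL_NAMES),
                           drop = TRUE),
                     function(d) raw_channel(d$channel[1L], d$t_s, d$value))
  vo2 <- meta[["vo2max"]]
  vo2 <- if (is.null(vo2) || !nzchar(vo2)) NA_real_ else as.numeric(vo2)
  dur <- meta[["duration"]]
  dur <- if (is.null(dur) || !nzchar(dur)) NULL else as.numeric(dur)
  run_session(meta$session_id, meta$date, as.numeric(meta$age),
              unname(channels), vo2max = vo2, duration = dur)
}

#' Write a session in the canonical long-format CSV
#'
#' Serialization is deterministic (fixed channel order, `%.17g` numbers) so
#' that identical sessions produce byte-identical files and values survive a
#' read/write round trip exactly.
#'
#' @param session A [run_session()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_session_csv <- function(session, path) {
  stopifnot(inherits(session, "run_session"))
  num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  header <- c(
    sprintf("# session_id=%s", session$session_id),
    sprintf("# date=%s", session$date),
    sprintf("# age=%s", num(session$age)),
    sprintf("# vo2max=%s", num(session$vo2max)),
    sprintf("# duration=%s", num(session$duration)),
    "channel,t_s,value")
  rows <- unlist(lapply(CHANNEL_NAMES, function(nm) {
    ch <- session$channels[[nm]]
    if (is.null(ch)) return(character(0))
    sprintf("%s,%s,%s", nm, num(ch$timestamps), num(ch$values))
  }))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Resample a raw channel onto a uniform grid
#'
#' Linear interpolation from the first to the last observed timestamp; no
#' extrapolation beyond the observed range (the grid stops at the last
#' observation).
#'
#' @param channel A [raw_channel()] with at least two samples.
#' @param dt Grid step in seconds (default 1, the reference device rate).
#' @return A [uniform_series()] starting at the channel's first timestamp.
#' @export
resample_uniform <- function(channel, dt = 1) {
  stopifnot(inherits(channel, "raw_channel"))
  if (length(channel$values) < 2L)
    stop("channel '", channel$name, "': need >= 2 samples to resample")
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0")
  t1 <- channel$timestamps[1L]
  t2 <- channel$timestamps[length(channel$timestamps)]
  grid <- seq(t1, t2, by = dt)
  vals <- stats::approx(channel$timestamps, channel$values, xout = grid,
                        method = "linear", rule = 1)$y
  uniform_series(vals, t0 = t1, dt = dt)
}

#' Split a raw channel at long sampling gaps
#'
#' Gaps longer than `max_gap_s` are never interpolated across; the channel is
#' split into contiguous segments instead.
#'
#' @param channel A [raw_channel()].
#' @param max_gap_s Largest tolerated sampling gap in seconds (default 30).
#' @return List of [raw_channel()] segments (singletons included).
#' @export
split_channel_gaps <- function(channel, max_gap_s = 30) {
  stopifnot(inherits(channel, "raw_channel"))
  n <- length(channel$timestamps)
  if (n <= 1L) return(list(channel))
  brk <- which(diff(channel$timestamps) > max_gap_s)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n)
  lapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    raw_channel(channel$name, channel$timestamps[idx], channel$values[idx])
  })
}

#' Align the three channels of a session onto one common 1 Hz grid
#'
#' Each channel is resampled with [resample_uniform()]; the common grid is the
#' intersection of the channels' observed time ranges.
#'
#' @param session A [run_session()].
#' @param dt Grid step in seconds.
#' @return Named list of [uniform_series()] on a shared grid.
#' @export
align_session <- function(session, dt = 1) {
  stopifnot(inherits(session, "run_session"))
  chans <- session$channels
  t_lo <- max(vapply(chans, function(ch) ch$timestamps[1L], numeric(1)))
  t_hi <- min(vapply(chans, function(ch) ch$timestamps[length(ch$timestamps)],
                     numeric(1)))
  if (t_hi - t_lo < dt)
    stop("channels do not overlap in time; cannot align")
  grid <- seq(t_lo, t_hi, by = dt)
  out <- lapply(chans, function(ch) {
    vals <- stats::approx(ch$timestamps, ch$values, xout = grid,
                          method = "linear", rule = 1)$y
    uniform_series(vals, t0 = t_lo, dt = dt)
  })
  out
}
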
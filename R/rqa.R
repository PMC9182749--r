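# Recurrence quantification analysis of heart-rate series: time-delay
# embedding, recurrence matrix, recurrence rate (RR) and determinism (DET),
# and DET trends across session thirds.  DET — the fraction of recurrence
# points lying on diagonal lines of length >= lmin — rises with signal
# regularity and is the fatigue-related readout.

#' RQA configuration
#'
#' @param m Embedding dimension (default 7).
#' @param tau Embedding lag in samples (default 1).
#' @param eps Recurrence radius (default 5): an absolute Euclidean distance
#'   in embedded space (bpm units for HR) when `radius_mode = "absolute"`,
#'   or a percentage of the maximum embedded distance when `"percent"`.
#' @param lmin Minimum diagonal line length (default 4).
#' @param theiler Theiler window: diagonals with `|i - j| < theiler` are
#'   excluded from recurrence statistics (default 1, i.e. only the line of
#'   identity).
#' @param radius_mode `"absolute"` or `"percent"`.
#' @return A list of class `rqa_config`.
#' @export
rqa_config <- function(m = 7, tau = 1, eps = 5, lmin = 4, theiler = 1,
                       radius_mode = c("absolute", "percent")) {
  radius_mode <- match.arg(radius_mode)
  stopifnot(m >= 1, tau >= 1, eps > 0, lmin >= 2, theiler >= 1)
  structure(list(m = as.integer(m), tau = as.integer(tau), eps = eps,
                 lmin = as.integer(lmin), theiler = as.integer(theiler),
                 radius_mode = radius_mode),
            class = "rqa_config")
}

#' Time-delay embedding
#'
#' @param x Numeric vector or [uniform_series()] of length at least
#'   `(m - 1) * tau + 1`.
#' @param m Embedding dimension.
#' @param tau Lag in samples.
#' @return Matrix with `length(x) - (m - 1) * tau` rows of dimension `m`;
#'   row i is `(x[i], x[i + tau], ..., x[i + (m-1) tau])`.
#' @export
embed_series <- function(x, m = 7, tau = 1) {
  if (inherits(x, "uniform_series")) x <- x$values
  n <- length(x)
  N <- n - (m - 1) * tau
  if (N < 1) stop("series too short to embed: need >= ", (m - 1) * tau + 1,
                  " samples")
  idx <- outer(seq_len(N), (0:(m - 1)) * tau, `+`)
  matrix(x[idx], nrow = N, ncol = m)
}

#' Recurrence matrix
#'
#' `R[i, j] = 1` iff the Euclidean distance between embedded vectors i and j
#' is at most the radius.  The matrix is symmetric with a unit diagonal; the
#' Theiler band is stored but excluded from line statistics downstream.
#'
#' @param embedded Matrix of embedded vectors (>= 2 rows).
#' @param eps Radius (see [rqa_config()]).
#' @param radius_mode `"absolute"` or `"percent"`.
#' @return Integer 0/1 matrix.
#' @export
recurrence_matrix <- function(embedded, eps = 5,
                              radius_mode = c("absolute", "percent")) {
  radius_mode <- match.arg(radius_mode)
  if (nrow(embedded) < 2) stop("need >= 2 embedded vectors")
  D <- as.matrix(stats::dist(embedded))
  if (radius_mode == "percent") eps <- eps / 100 * max(D)
  R <- (D <= eps) * 1L
  storage.mode(R) <- "integer"
  R
}

# Diagonal line-length histogram off the Theiler band (upper triangle; the
# matrix is symmetric so each line is counted once per side).
.diag_line_hist <- function(R, theiler = 1) {
  N <- nrow(R)
  lens <- integer(0)
  if (theiler <= N - 1) {
    for (d in theiler:(N - 1)) {
      v <- R[cbind(seq_len(N - d), seq_len(N - d) + d)]
      r <- rle(v)
      lens <- c(lens, r$lengths[r$values == 1L])
    }
  }
  lens
}

#' Determinism and diagonal line histogram
#'
#' `DET = sum_{l >= lmin} l P(l) / sum_{l >= 1} l P(l)` over diagonal line
#' lengths outside the Theiler band; defined as 0 (flagged) when there are
#' no recurrence points at all.
#'
#' @param R Binary recurrence matrix.
#' @param lmin Minimum line length (default 4).
#' @param theiler Theiler window (default 1).
#' @return List with `det`, `line_lengths` (integer vector of diagonal line
#'   lengths), `degenerate` (TRUE when 0/0).
#' @export
determinism <- function(R, lmin = 4, theiler = 1) {
  lens <- .diag_line_hist(R, theiler)
  total <- sum(lens)
  if (total == 0)
    return(list(det = 0, line_lengths = lens, degenerate = TRUE))
  list(det = sum(lens[lens >= lmin]) / total, line_lengths = lens,
       degenerate = FALSE)
}

#' Recurrence rate
#'
#' Fraction of recurrent pairs among all pairs outside the Theiler band.
#'
#' @param R Binary recurrence matrix.
#' @param theiler Theiler window.
#' @return Recurrence rate in `[0, 1]`.
#' @export
recurrence_rate <- function(R, theiler = 1) {
  N <- nrow(R)
  off <- abs(row(R) - col(R)) >= theiler
  if (!any(off)) return(0)
  sum(R[off]) / sum(off)
}

#' Full RQA of a uniform series
#'
#' @param series A [uniform_series()] or numeric vector.
#' @param config An [rqa_config()].
#' @param keep_matrix Store the recurrence matrix in the result (default
#'   TRUE for up to 5000 embedded points; larger matrices are dropped and
#'   only the statistics kept).
#' @return Object of class `rqa_result`: `n_embedded`, `rr`, `det`,
#'   `line_lengths`, `matrix` (or NULL), `config`.
#' @export
rqa_analyze <- function(series, config = rqa_config(), keep_matrix = NULL) {
  E <- embed_series(series, config$m, config$tau)
  R <- recurrence_matrix(E, config$eps, config$radius_mode)
  d <- determinism(R, config$lmin, config$theiler)
  rr <- recurrence_rate(R, config$theiler)
  if (is.null(keep_matrix)) keep_matrix <- nrow(R) <= 5000
  structure(list(n_embedded = nrow(R), rr = rr, det = d$det,
                 line_lengths = d$line_lengths,
                 degenerate = d$degenerate,
                 matrix = if (keep_matrix) R,
                 config = config),
            class = "rqa_result")
}

#' @export
print.rqa_result <- function(x, ...) {
  cat(sprintf("<rqa_result: %d embedded points, RR = %.4f, DET = %.4f>\n",
              x$n_embedded, x$rr, x$det))
  invisible(x)
}

#' Recurrence plot
#'
#' @param x An `rqa_result` with a stored matrix.
#' @param ... Passed to [graphics::image()].
#' @export
plot.rqa_result <- function(x, ...) {
  if (is.null(x$matrix)) stop("recurrence matrix was not stored")
  graphics::image(seq_len(nrow(x$matrix)), seq_len(ncol(x$matrix)),
                  t(x$matrix[nrow(x$matrix):1, ]),
                  col = c("white", "black"), xlab = "i", ylab = "j",
                  useRaster = TRUE, ...)
  invisible(x)
}

#' DET per session third
#'
#' Splits the series into thirds of normalized time and runs RQA on each.
#'
#' @param hr A [uniform_series()] (typically the cleaned intense-zone HR).
#' @param config An [rqa_config()].
#' @return Data.frame with columns `section`, `n_embedded`, `rr`, `det`;
#'   a third too short to embed is flagged with `NA` statistics.
#' @export
section_det <- function(hr, config = rqa_config()) {
  stopifnot(inherits(hr, "uniform_series"))
  x <- hr$values
  n <- length(x)
  bounds <- round(n * c(0, 1 / 3, 2 / 3, 1))
  secs <- c("start", "middle", "end")
  rows <- lapply(1:3, function(i) {
    seg <- x[(bounds[i] + 1):bounds[i + 1]]
    if (length(seg) < (config$m - 1) * config$tau + 2) {
      warning("section '", secs[i], "' too short for RQA; flagged missing")
      return(data.frame(section = secs[i], n_embedded = NA_integer_,
                        rr = NA_real_, det = NA_real_))
    }
    r <- rqa_analyze(seg, config, keep_matrix = FALSE)
    data.frame(section = secs[i], n_embedded = r$n_embedded, rr = r$rr,
               det = r$det)
  })
  do.call(rbind, rows)
}
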
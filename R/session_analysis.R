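# Per-session and cohort summaries: regime frequencies, independent
# (non-overlapping) window subsets for hypothesis tests, start/middle/end
# section analysis, VO2max correlation, and group-difference testing.

#' Regime frequencies of a labelled session
#'
#' @param labels Character vector of sign labels (`"+/+"`, `"+/-"`,
#'   `"-/+"`, `"-/-"`), one per window.
#' @param session_id,date,vo2max Optional session metadata carried along.
#' @return An object of class `session_cluster_summary`: a one-row
#'   data.frame with `session_id`, `date`, `vo2max`, `n_windows` and one
#'   frequency column per sign label (`freq_pp`, `freq_pm`, `freq_mp`,
#'   `freq_mm`); absent labels get frequency 0 and frequencies sum to 1.
#' @export
cluster_frequencies <- function(labels, session_id = NA_character_,
                                date = NA_character_, vo2max = NA_real_) {
  if (!length(labels)) stop("no labelled windows")
  bad <- setdiff(unique(labels), SIGN_LABELS)
  if (length(bad)) stop("unknown sign label: ", bad[1L])
  tab <- table(factor(labels, levels = SIGN_LABELS)) / length(labels)
  out <- data.frame(session_id = session_id, date = date, vo2max = vo2max,
                    n_windows = length(labels),
                    freq_pp = as.numeric(tab["+/+"]),
                    freq_pm = as.numeric(tab["+/-"]),
                    freq_mp = as.numeric(tab["-/+"]),
                    freq_mm = as.numeric(tab["-/-"]))
  class(out) <- c("session_cluster_summary", "data.frame")
  out
}

freq_column <- function(label) {
  c("+/+" = "freq_pp", "+/-" = "freq_pm",
    "-/+" = "freq_mp", "-/-" = "freq_mm")[[label]]
}

#' Non-overlapping window subset
#'
#' Greedy selection from the first window onward with stride equal to the
#' window width, giving pairwise-disjoint windows for statistics on
#' independent points.
#'
#' @param features A [window_features()] data.frame (any extra columns are
#'   kept), sorted by `window_start_s`.
#' @param width_s Window width in seconds; defaults to the `width_s` column.
#' @return The subset of rows whose windows do not overlap.
#' @export
nonoverlapping_subset <- function(features, width_s = NULL) {
  if (!nrow(features)) return(features)
  if (is.null(width_s)) width_s <- features$width_s[1L]
  starts <- features$window_start_s
  if (is.unsorted(starts)) {
    o <- order(starts)
    features <- features[o, , drop = FALSE]
    starts <- starts[o]
  }
  keep <- logical(length(starts))
  next_ok <- -Inf
  for (i in seq_along(starts)) {
    if (starts[i] >= next_ok) {
      keep[i] <- TRUE
      next_ok <- starts[i] + width_s
    }
  }
  features[keep, , drop = FALSE]
}

#' Section (start/middle/end) regime frequencies
#'
#' The session is split into thirds of normalized time; each window is
#' assigned to the section containing its midpoint.
#'
#' @param labels Sign label per window.
#' @param window_start_s Window start times in seconds.
#' @param width_s Window width in seconds.
#' @param duration_s Session duration in seconds (normalization basis).
#' @return A data.frame of class `section_summary` with one row per section
#'   (`start`, `middle`, `end`): `n_windows` and per-label frequency
#'   columns; a section without windows has `NA` frequencies.
#' @export
section_frequencies <- function(labels, window_start_s, width_s, duration_s) {
  stopifnot(length(labels) == length(window_start_s), duration_s > 0)
  if (!length(labels)) stop("no labelled windows")
  mid <- (window_start_s + width_s / 2) / duration_s
  section <- cut(mid, breaks = c(-Inf, 1 / 3, 2 / 3, Inf),
                 labels = c("start", "middle", "end"), right = FALSE)
  rows <- lapply(levels(section), function(sec) {
    in_sec <- section == sec
    if (!any(in_sec)) {
      warning("section '", sec, "' contains no windows")
      return(data.frame(section = sec, n_windows = 0L, freq_pp = NA_real_,
                        freq_pm = NA_real_, freq_mp = NA_real_,
                        freq_mm = NA_real_))
    }
    tab <- table(factor(labels[in_sec], levels = SIGN_LABELS)) / sum(in_sec)
    data.frame(section = sec, n_windows = sum(in_sec),
               freq_pp = as.numeric(tab["+/+"]),
               freq_pm = as.numeric(tab["+/-"]),
               freq_mp = as.numeric(tab["-/+"]),
               freq_mm = as.numeric(tab["-/-"]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("section_summary", "data.frame")
  out
}

#' Correlate regime frequencies with VO2max across sessions
#'
#' Pearson correlation (two-sided test) between the per-session frequency of
#' each sign label and the session VO2max.
#'
#' @param summaries A data.frame stacking [cluster_frequencies()] rows (one
#'   per session) with a `vo2max` column; sessions lacking VO2max are
#'   dropped with a warning.
#' @return A data.frame of class `correlation_report` with columns `label`,
#'   `r`, `p_value`, `n`; `r` is `NA` (flagged by a warning) when either
#'   variable is constant.
#' @export
correlate_vo2max <- function(summaries) {
  df <- as.data.frame(summaries)
  miss <- is.na(df$vo2max)
  if (any(miss)) {
    warning(sum(miss), " session(s) without vo2max excluded from correlation")
    df <- df[!miss, , drop = FALSE]
  }
  if (nrow(df) < 3) stop("need >= 3 sessions with vo2max")
  rows <- lapply(SIGN_LABELS, function(lab) {
    f <- df[[freq_column(lab)]]
    if (stats::sd(f) == 0 || stats::sd(df$vo2max) == 0) {
      warning("constant frequency or vo2max for cluster ", lab,
              ": correlation undefined")
      return(data.frame(label = lab, r = NA_real_, p_value = NA_real_,
                        n = nrow(df)))
    }
    ct <- stats::cor.test(f, df$vo2max, method = "pearson")
    data.frame(label = lab, r = unname(ct$estimate),
               p_value = ct$p.value, n = nrow(df))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_report", "data.frame")
  out
}

#' Significance stars for p-values
#'
#' Bins follow the usual annotation legend: ns, *, **, ***, ****.
#'
#' @param p Numeric p-values.
#' @return Character vector of annotations.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

#' Omnibus and post-hoc group-difference tests
#'
#' Normality is gated per group with Shapiro-Wilk at 0.05.  If every group
#' passes, the omnibus test is a one-way ANOVA with pairwise t-tests
#' post-hoc (Tukey-style pooled SD); otherwise Kruskal-Wallis with pairwise
#' Mann-Whitney-Wilcoxon.  Post-hoc p-values are Bonferroni-adjusted.  A
#' repeated-measures design uses the subject as a blocking factor (ANOVA
#' with an error stratum, or paired post-hoc tests).
#'
#' @param values Numeric observations.
#' @param groups Group factor (>= 2 levels, >= 3 observations each).
#' @param design `"independent"` or `"repeated"`.
#' @param subject Subject identifier, required for `design = "repeated"`.
#' @return List of class `group_test_report`: `omnibus` (test name,
#'   statistic, p-value), `normal` (gate outcome), `posthoc` (data.frame of
#'   pairwise comparisons with raw and Bonferroni-adjusted p), `stars`.
#' @export
group_tests <- function(values, groups, design = c("independent", "repeated"),
                        subject = NULL) {
  design <- match.arg(design)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  sizes <- table(groups)
  if (any(sizes < 3)) stop("each group needs >= 3 observations")
  if (vapply(split(values, groups), function(v) stats::sd(v) == 0,
             logical(1)) |> all())
    stop("degenerate groups: zero variance everywhere")
  normal <- all(vapply(split(values, groups), function(v) {
    if (stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value > 0.05
  }, logical(1)))
  if (design == "repeated") {
    if (is.null(subject)) stop("'subject' required for repeated design")
    subject <- factor(subject)
    df <- data.frame(v = values, g = groups, s = subject)
    fit <- stats::aov(v ~ g + Error(s / g), data = df)
    tabs <- summary(fit)
    tab <- tabs[["Error: s:g"]][[1L]]
    omni <- list(test = "repeated-measures ANOVA",
                 statistic = tab["g", "F value"],
                 p_value = tab["g", "Pr(>F)"])
    pairs <- utils::combn(levels(groups), 2)
    ph <- apply(pairs, 2, function(pr) {
      a <- df[df$g == pr[1], ]; b <- df[df$g == pr[2], ]
      a <- a[order(a$s), ]; b <- b[order(b$s), ]
      if (normal) stats::t.test(a$v, b$v, paired = TRUE)$p.value
      else stats::wilcox.test(a$v, b$v, paired = TRUE, exact = FALSE)$p.value
    })
  } else {
    if (normal) {
      fit <- stats::aov(values ~ groups)
      tab <- summary(fit)[[1L]]
      omni <- list(test = "one-way ANOVA",
                   statistic = tab["groups", "F value"],
                   p_value = tab["groups", "Pr(>F)"])
    } else {
      kw <- stats::kruskal.test(values, groups)
      omni <- list(test = "Kruskal-Wallis",
                   statistic = unname(kw$statistic), p_value = kw$p.value)
    }
    pairs <- utils::combn(levels(groups), 2)
    ph <- apply(pairs, 2, function(pr) {
      a <- values[groups == pr[1]]; b <- values[groups == pr[2]]
      if (normal) stats::t.test(a, b)$p.value
      else stats::wilcox.test(a, b, exact = FALSE)$p.value
    })
  }
  m <- length(ph)
  posthoc <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                        p_raw = as.numeric(ph),
                        p_adj = pmin(1, m * as.numeric(ph)))
  posthoc$stars <- p_stars(posthoc$p_adj)
  structure(list(omnibus = omni, normal = normal, posthoc = posthoc,
                 design = design),
            class = "group_test_report")
}

#' @export
print.group_test_report <- function(x, ...) {
  cat(sprintf("<group_test_report: %s, statistic = %.4g, p = %.4g (%s)>\n",
              x$omnibus$test, x$omnibus$statistic, x$omnibus$p_value,
              p_stars(x$omnibus$p_value)))
  print(x$posthoc)
  invisible(x)
}
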
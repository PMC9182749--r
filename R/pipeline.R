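# End-to-end orchestration of the analysis: clean -> align -> (optional
# window estimate) -> energy -> window features -> scale -> cluster -> sign
# labels -> frequencies / sections -> RQA, plus the cohort-level summary.

#' Pipeline configuration
#'
#' @param cleaning A [cleaning_config()].
#' @param rqa A [rqa_config()].
#' @param width_s Sliding-window width in seconds (NULL: estimate from the
#'   data via [estimate_window_width()]).
#' @param dt Uniform grid step in seconds.
#' @param alpha Feature-scaling multiplier (see [scale_features()]).
#' @param k Number of clusters when `select_k = FALSE` (default 4, the four
#'   heartbeat-dynamics regimes).
#' @param select_k Choose k by silhouette over `k_range` instead of fixing
#'   it.
#' @param k_range Candidate k values for silhouette selection.
#' @param n_init k-means++ restarts.
#' @param g Gravitational acceleration in m/s^2.
#' @param seed RNG seed threaded through clustering.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cleaning = cleaning_config(), rqa = rqa_config(),
                            width_s = 90, dt = 1, alpha = 3, k = 4,
                            select_k = FALSE, k_range = 2:10, n_init = 10,
                            g = 9.80665, seed = 1L) {
  structure(list(cleaning = cleaning, rqa = rqa, width_s = width_s, dt = dt,
                 alpha = alpha, k = k, select_k = select_k,
                 k_range = k_range, n_init = n_init, g = g, seed = seed),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Analyze a single running session
#'
#' Runs the full single-session pipeline and returns every intermediate
#' artifact.  With `out_dir` set, the feature table, window labels, section
#' and RQA summaries (CSV) and the cluster model (JSON) are also written.
#'
#' @param session A [run_session()] or a path to a canonical session CSV.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for artifacts.
#' @return Object of class `session_result`: `session`, `clean`, `energy`,
#'   `features`, `scaled`, `model`, `window_labels` (data.frame
#'   window_start_s/label), `summary` (regime frequencies), `sections`,
#'   `rqa_sections`, `width_s`, `config`.  When no analyzable intense-zone
#'   segment exists, a degenerate result with `n_windows = 0` and
#'   `status = "no_analyzable_segments"` is returned instead of an error.
#' @export
run_single_session <- function(session, config = pipeline_config(),
                               out_dir = NULL) {
  if (is.character(session))
    session <- stage("read", read_session_csv(session))
  stopifnot(inherits(session, "run_session"))
  cl <- stage("clean", clean_session(session, config$cleaning,
                                     dt = config$dt))
  if (!nrow(cl$zone$segments)) {
    return(structure(list(session = session, clean = cl,
                          status = "no_analyzable_segments",
                          summary = NULL, width_s = config$width_s,
                          config = config),
                     class = "session_result"))
  }
  width <- config$width_s
  if (is.null(width)) {
    est <- stage("window_estimate", estimate_window_width(session,
                                                          dt = config$dt))
    width <- est$chosen_width
  }
  if (is.null(cl$speed) || is.null(cl$altitude))
    stop("stage 'energy': session lacks speed or altitude channel")
  energy <- stage("energy", compute_energy(cl$altitude, cl$speed,
                                           g = config$g))
  feats <- stage("features",
                 window_features(cl$hr, energy, width_s = width,
                                 segments = cl$zone$segments))
  if (!nrow(feats))
    return(structure(list(session = session, clean = cl,
                          status = "no_analyzable_segments",
                          summary = NULL, width_s = width, config = config),
                     class = "session_result"))
  sc <- stage("scale", scale_features(feats, alpha = config$alpha))
  model <- stage("cluster", {
    if (config$select_k) {
      sel <- select_k(sc$points, k_range = config$k_range,
                      n_init = config$n_init, seed = config$seed)
      sel$models[[which(sel$scores$k == sel$chosen_k)]]
    } else {
      m <- kmeans_dynamics(sc$points, config$k, n_init = config$n_init,
                           seed = config$seed)
      m$mean_silhouette <- silhouette_values(sc$points, m$labels)$mean
      m
    }
  })
  model <- stage("sign_labels", assign_sign_labels(model, sc$scaling))
  labels <- model$sign_labels[model$labels]
  window_labels <- data.frame(window_start_s = feats$window_start_s,
                              label = labels)
  summ <- stage("frequencies",
                cluster_frequencies(labels, session_id = session$session_id,
                                    date = session$date,
                                    vo2max = session$vo2max))
  sections <- stage("sections",
                    section_frequencies(labels, feats$window_start_s, width,
                                        duration_s = session$duration))
  zone_hr <- zone_series(cl)
  rqa_sec <- stage("rqa", section_det(zone_hr, config$rqa))
  res <- structure(list(session = session, clean = cl, energy = energy,
                        features = feats, scaled = sc, model = model,
                        window_labels = window_labels, summary = summ,
                        sections = sections, rqa_sections = rqa_sec,
                        width_s = width, status = "ok", config = config),
                   class = "session_result")
  if (!is.null(out_dir)) write_session_artifacts(res, out_dir)
  res
}

# Concatenated intense-zone HR (retained segments only).
zone_series <- function(clean) {
  segs <- clean$zone$segments
  idx <- unlist(lapply(seq_len(nrow(segs)),
                       function(i) segs$start_idx[i]:segs$end_idx[i]))
  uniform_series(clean$hr$values[idx], t0 = clean$hr$t0, dt = clean$hr$dt)
}

write_session_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_features_csv(res$features, p("features.csv"))
  utils::write.csv(res$window_labels, p("window_labels.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$summary), p("frequencies.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$sections), p("sections.csv"),
                   row.names = FALSE)
  utils::write.csv(res$rqa_sections, p("rqa_sections.csv"),
                   row.names = FALSE)
  write_model_json(res$model, res$scaled$scaling, p("model.json"))
  invisible(out_dir)
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result '%s': %s>\n", x$session$session_id, x$status))
  if (identical(x$status, "ok")) {
    cat(sprintf("  %d windows of %g s; regime frequencies:\n",
                x$summary$n_windows, x$width_s))
    print(round(unlist(x$summary[c("freq_pp", "freq_pm", "freq_mp",
                                   "freq_mm")]), 3))
  }
  invisible(x)
}

#' Analyze a cohort of sessions
#'
#' Runs [run_single_session()] on every session, stacks the per-session
#' regime frequencies and correlates them with VO2max.  Invalid session
#' files and sessions without analyzable segments are skipped with a
#' warning.
#'
#' @param sessions List of [run_session()] objects, or a directory of
#'   canonical session CSV files.
#' @param config A [pipeline_config()].
#' @return Object of class `cohort_report`: `results` (per-session),
#'   `summaries` (stacked frequencies), `correlation` (from
#'   [correlate_vo2max()], NULL when fewer than 3 sessions carry VO2max).
#' @export
run_cohort <- function(sessions, config = pipeline_config()) {
  if (is.character(sessions)) {
    files <- list.files(sessions, pattern = "\\.csv$", full.names = TRUE)
    sessions <- list()
    for (f in files) {
      s <- tryCatch(read_session_csv(f), error = function(e) {
        warning("skipping '", basename(f), "': ", conditionMessage(e))
        NULL
      })
      if (!is.null(s)) sessions <- c(sessions, list(s))
    }
  }
  if (length(sessions) < 3) stop("need >= 3 sessions for a cohort analysis")
  results <- list(); summaries <- list()
  for (s in sessions) {
    r <- tryCatch(run_single_session(s, config), error = function(e) {
      warning("session '", s$session_id, "' failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(r) || !identical(r$status, "ok")) {
      if (!is.null(r))
        warning("session '", s$session_id, "': no analyzable segments")
      next
    }
    results[[length(results) + 1L]] <- r
    summaries[[length(summaries) + 1L]] <- as.data.frame(r$summary)
  }
  if (!length(summaries)) stop("no session produced an analyzable summary")
  summaries <- do.call(rbind, summaries)
  correlation <- if (sum(!is.na(summaries$vo2max)) >= 3)
    correlate_vo2max(summaries)
  structure(list(results = results, summaries = summaries,
                 correlation = correlation, config = config),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report: %d analyzed sessions>\n", nrow(x$summaries)))
  if (!is.null(x$correlation)) print(as.data.frame(x$correlation))
  invisible(x)
}
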
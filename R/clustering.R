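# Clustering of windows in the (Delta E, Delta HR) plane: per-axis rescaling
# into roughly [-1, 1], Lloyd/Forgy k-means with k-means++ initialization and
# an L2 objective, silhouette-based selection of k, and sign labelling of the
# four heartbeat-dynamics regimes.

SIGN_LABELS <- c("+/+", "+/-", "-/+", "-/-")

#' Rescale features into the clustering plane
#'
#' Each axis is mapped as `x -> (x - mean) / (alpha * s)` with `s` the axis
#' SD.  For nearly Gaussian features `alpha = 3` maps more than 99% of
#' points into the `[-1, 1]^2` square; when coverage falls short, `alpha` is
#' raised by direct calculation from the empirical quantiles until at least
#' 99% of the points are covered.
#'
#' @param features A [window_features()] data.frame (>= 2 windows).
#' @param alpha Initial scale multiplier (default 3).
#' @return List with `points` (n x 2 matrix, columns `delta_e`, `delta_hr`)
#'   and `scaling`, an object of class `feature_scaling` with fields
#'   `mean_e`, `mean_hr`, `s_e`, `s_hr`, `alpha`, `coverage`.
#' @export
scale_features <- function(features, alpha = 3) {
  de <- features$delta_e; dh <- features$delta_hr
  if (length(de) < 2) stop("need >= 2 windows to scale")
  if (!all(is.finite(de)) || !all(is.finite(dh)))
    stop("non-finite feature values")
  m_e <- mean(de); m_h <- mean(dh)
  s_e <- stats::sd(de); s_h <- stats::sd(dh)
  if (s_e == 0 || s_h == 0) stop("zero SD on a feature axis; cannot scale")
  # Worst-axis absolute z-score per point; alpha must exceed its 99th
  # percentile for [-1,1]^2 coverage >= 0.99.
  zmax <- pmax(abs(de - m_e) / s_e, abs(dh - m_h) / s_h)
  needed <- sort(zmax)[ceiling(0.99 * length(zmax))]
  alpha_final <- max(alpha, needed)
  pts <- cbind(delta_e = (de - m_e) / (alpha_final * s_e),
               delta_hr = (dh - m_h) / (alpha_final * s_h))
  coverage <- mean(abs(pts[, 1]) <= 1 & abs(pts[, 2]) <= 1)
  scaling <- structure(list(mean_e = m_e, mean_hr = m_h, s_e = s_e,
                            s_h = s_h, alpha = alpha_final,
                            coverage = coverage),
                       class = "feature_scaling")
  list(points = pts, scaling = scaling)
}

#' Map scaled points back to raw feature units
#'
#' @param points n x 2 matrix in the scaled plane.
#' @param scaling A `feature_scaling` from [scale_features()].
#' @return n x 2 matrix in raw (Delta E, Delta HR) units.
#' @export
unscale_points <- function(points, scaling) {
  cbind(delta_e = points[, 1] * scaling$alpha * scaling$s_e + scaling$mean_e,
        delta_hr = points[, 2] * scaling$alpha * scaling$s_h + scaling$mean_hr)
}

# Squared Euclidean distances from every point to every centroid.
.dist2_to_centroids <- function(pts, centers) {
  outer(rowSums(pts^2), rep(1, nrow(centers))) -
    2 * pts %*% t(centers) +
    outer(rep(1, nrow(pts)), rowSums(centers^2))
}

# k-means++ seeding: first centroid uniform, then D^2 sampling.
.kmeanspp_init <- function(pts, k) {
  n <- nrow(pts)
  centers <- matrix(NA_real_, k, ncol(pts))
  centers[1, ] <- pts[sample.int(n, 1L), ]
  d2 <- rowSums((pts - matrix(centers[1, ], n, ncol(pts), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      centers[j, ] <- pts[sample.int(n, 1L), ]
    } else {
      centers[j, ] <- pts[sample.int(n, 1L, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums((pts - matrix(centers[j, ], n, ncol(pts),
                                         byrow = TRUE))^2))
  }
  centers
}

#' k-means clustering (Lloyd/Forgy with k-means++ starts)
#'
#' Minimizes the total intracluster squared error
#' `E(C) = sum_j sum_{x in C_j} ||x - c_j||^2`.  Each of `n_init` runs starts
#' from k-means++ seeds and iterates assignment/update until no point is
#' reassigned or the largest centroid shift falls below `tol`.  A cluster
#' emptied during iteration is re-seeded at the point farthest from its
#' former centroid.  The best run by the objective is returned.
#'
#' @param points n x 2 (or n x d) numeric matrix.
#' @param k Number of clusters (k <= n).
#' @param tol Convergence tolerance on centroid displacement (default 1e-5).
#' @param n_init Number of k-means++ restarts (default 10).
#' @param seed Optional RNG seed for reproducible initialization.
#' @param max_iter Iteration cap per run.
#' @return An object of class `cluster_model` with `k`, `centroids` (scaled
#'   space), `labels`, `objective`, `objective_trace` (per accepted run),
#'   `iterations`, `mean_silhouette` (NA until computed), `sign_labels`
#'   (NA until [assign_sign_labels()]).
#' @export
kmeans_dynamics <- function(points, k, tol = 1e-5, n_init = 10, seed = NULL,
                            max_iter = 200) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (k > n) stop("k = ", k, " exceeds the number of points (", n, ")")
  if (k < 1) stop("k must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (run in seq_len(n_init)) {
    centers <- .kmeanspp_init(pts, k)
    labels <- rep(0L, n)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      d2 <- .dist2_to_centroids(pts, centers)
      new_labels <- max.col(-d2, ties.method = "first")
      trace <- c(trace, sum(d2[cbind(seq_len(n), new_labels)]))
      no_reassign <- identical(new_labels, labels)
      labels <- new_labels
      new_centers <- centers
      for (j in seq_len(k)) {
        in_j <- labels == j
        if (!any(in_j)) {
          # empty cluster: relocate to the farthest point from its former
          # centroid
          far <- which.max(rowSums((pts - matrix(centers[j, ], n, ncol(pts),
                                                 byrow = TRUE))^2))
          new_centers[j, ] <- pts[far, ]
        } else {
          new_centers[j, ] <- colMeans(pts[in_j, , drop = FALSE])
        }
      }
      shift <- sqrt(max(rowSums((new_centers - centers)^2)))
      centers <- new_centers
      if (no_reassign || shift < tol) break
    }
    d2 <- .dist2_to_centroids(pts, centers)
    labels <- max.col(-d2, ties.method = "first")
    obj <- sum(d2[cbind(seq_len(n), labels)])
    if (is.null(best) || obj < best$objective)
      best <- list(centers = centers, labels = labels, objective = obj,
                   trace = trace, iterations = it)
  }
  structure(list(k = k, centroids = best$centers, labels = best$labels,
                 objective = best$objective,
                 objective_trace = best$trace,
                 iterations = best$iterations,
                 mean_silhouette = NA_real_,
                 sign_labels = NULL),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model: k = %d, n = %d, objective = %.6g, mean silhouette = %s>\n",
              x$k, length(x$labels), x$objective,
              if (is.na(x$mean_silhouette)) "NA"
              else sprintf("%.3f", x$mean_silhouette)))
  if (!is.null(x$sign_labels))
    cat("  sign labels:", paste(x$sign_labels, collapse = " "), "\n")
  invisible(x)
}

#' Silhouette values and score
#'
#' For each point, `a_i` is the mean distance to the other members of its
#' cluster (divisor `n_A - 1`), `b_i` the smallest mean distance to any
#' other cluster, and `s_i = (b_i - a_i) / max(a_i, b_i)`.  Points in
#' singleton clusters get `s_i = 0`.
#'
#' @param points n x d numeric matrix.
#' @param labels Integer/character cluster labels (>= 2 distinct).
#' @return An object of class `silhouette_report` with `s` (per point),
#'   `mean`, `a`, `b`, `labels`.
#' @export
silhouette_values <- function(points, labels) {
  pts <- as.matrix(points)
  labs <- as.integer(factor(labels))
  n <- nrow(pts)
  if (length(labs) != n) stop("labels length mismatch")
  kk <- max(labs)
  if (kk < 2) stop("need >= 2 clusters for silhouettes")
  D <- as.matrix(stats::dist(pts))
  sizes <- tabulate(labs, kk)
  # column j of sums: total distance from each point to cluster j
  sums <- sapply(seq_len(kk), function(j)
    rowSums(D[, labs == j, drop = FALSE]))
  a <- numeric(n); b <- numeric(n); s <- numeric(n)
  for (i in seq_len(n)) {
    g <- labs[i]
    if (sizes[g] == 1L) { s[i] <- 0; a[i] <- 0; b[i] <- NA_real_; next }
    a[i] <- sums[i, g] / (sizes[g] - 1L)
    others <- setdiff(seq_len(kk), g)
    b[i] <- min(sums[i, others] / sizes[others])
    s[i] <- (b[i] - a[i]) / max(a[i], b[i])
  }
  structure(list(s = s, mean = mean(s), a = a, b = b, labels = labs),
            class = "silhouette_report")
}

#' @export
print.silhouette_report <- function(x, ...) {
  cat(sprintf("<silhouette_report: n = %d, mean = %.4f>\n",
              length(x$s), x$mean))
  invisible(x)
}

#' Select the number of clusters by the mean silhouette
#'
#' Runs [kmeans_dynamics()] for every `k` in `k_range` and picks the `k`
#' with the largest mean silhouette (ties broken toward the smallest `k`).
#'
#' @param points n x d numeric matrix.
#' @param k_range Candidate values of k (default 2:10; clipped to
#'   `[2, n - 1]` with a warning).
#' @param tol,n_init,seed Passed to [kmeans_dynamics()]; per-k seeds are
#'   derived from `seed`.
#' @return List with `chosen_k`, `scores` (data.frame k/mean_silhouette),
#'   `models` (per-k cluster models).
#' @export
select_k <- function(points, k_range = 2:10, tol = 1e-5, n_init = 10,
                     seed = NULL) {
  n <- nrow(as.matrix(points))
  rng <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(rng)) stop("no admissible k in k_range for n = ", n)
  if (length(rng) < length(k_range))
    warning("k_range clipped to [2, n - 1]")
  models <- list(); scores <- numeric(length(rng))
  for (i in seq_along(rng)) {
    k <- rng[i]
    mod <- kmeans_dynamics(points, k, tol = tol, n_init = n_init,
                           seed = if (is.null(seed)) NULL else seed + k)
    sil <- silhouette_values(points, mod$labels)
    mod$mean_silhouette <- sil$mean
    models[[i]] <- mod
    scores[i] <- sil$mean
  }
  best <- which(scores == max(scores))[1L]   # ties -> smallest k
  if (max(scores) < 0.5)
    warning("weak cluster structure: best mean silhouette ",
            sprintf("%.3f", max(scores)), " < 0.5")
  list(chosen_k = rng[best],
       scores = data.frame(k = rng, mean_silhouette = scores),
       models = models)
}

#' Sign-label the clusters of a fitted model
#'
#' Centroids are mapped back to raw (Delta E, Delta HR) units and labelled
#' `sign(Delta E)/sign(Delta HR)`; an exact zero counts as `+` (with a
#' warning).  With `k = 4` the four labels must be distinct.
#'
#' @param model A [kmeans_dynamics()] result fitted on scaled points.
#' @param scaling The [scale_features()] scaling.
#' @return The model with `sign_labels` (one per cluster index) and
#'   `centroids_raw` filled in.
#' @export
assign_sign_labels <- function(model, scaling) {
  stopifnot(inherits(model, "cluster_model"),
            inherits(scaling, "feature_scaling"))
  raw <- unscale_points(model$centroids, scaling)
  sgn <- function(x) {
    if (any(x == 0))
      warning("centroid coordinate exactly 0; sign(0) counts as '+'")
    ifelse(x >= 0, "+", "-")
  }
  labels <- paste0(sgn(raw[, 1]), "/", sgn(raw[, 2]))
  if (model$k == 4 && anyDuplicated(labels))
    stop("clusters not sign-separated: duplicate sign pair '",
         labels[duplicated(labels)][1L], "' at k = 4")
  model$sign_labels <- labels
  model$centroids_raw <- raw
  model
}

#' Export a cluster model as JSON
#'
#' @param model A sign-labelled [cluster_model].
#' @param scaling The [scale_features()] scaling.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(model, scaling, path) {
  obj <- list(k = model$k,
              centroids_scaled = unname(apply(model$centroids, 1, as.numeric,
                                              simplify = FALSE)),
              centroids_raw = if (!is.null(model$centroids_raw))
                unname(apply(model$centroids_raw, 1, as.numeric,
                             simplify = FALSE)),
              sign_labels = model$sign_labels,
              objective = model$objective,
              mean_silhouette = model$mean_silhouette,
              scaling = unclass(scaling))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
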
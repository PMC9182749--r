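# Independent oracles and small fixture builders shared across tests.

# Brute-force silhouette: explicit double loop over points and clusters,
# following the defining equations directly (a_i with divisor n_A - 1, b_i
# minimized over other clusters, s_i = (b_i - a_i) / max(a_i, b_i),
# singletons -> 0).  Deliberately scalar so it stays independent of the
# vectorized implementation.
brute_silhouette <- function(points, labels) {
  pts <- as.matrix(points)
  labs <- as.integer(factor(labels))
  n <- nrow(pts)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labs == labs[i])
    if (length(same) == 1L) { s[i] <- 0; next }
    a <- 0
    for (j in setdiff(same, i)) a <- a + sqrt(sum((pts[i, ] - pts[j, ])^2))
    a <- a / (length(same) - 1L)
    b <- Inf
    for (g in setdiff(unique(labs), labs[i])) {
      other <- which(labs == g)
      d <- 0
      for (j in other) d <- d + sqrt(sum((pts[i, ] - pts[j, ])^2))
      b <- min(b, d / length(other))
    }
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Brute-force determinism: explicit scan of every diagonal of the matrix
# (both triangles), run-length counting by hand.
brute_det <- function(R, lmin, theiler) {
  N <- nrow(R)
  total <- 0; det_sum <- 0
  offsets <- setdiff(-(N - 1):(N - 1), (-(theiler - 1)):(theiler - 1))
  for (d in offsets) {
    run <- 0L
    idx <- if (d >= 0) cbind(seq_len(N - d), seq_len(N - d) + d)
           else cbind(seq_len(N + d) - d, seq_len(N + d))
    v <- R[idx]
    for (x in c(v, 0L)) {
      if (x == 1L) run <- run + 1L
      else if (run > 0L) {
        total <- total + run
        if (run >= lmin) det_sum <- det_sum + run
        run <- 0L
      }
    }
  }
  if (total == 0) 0 else det_sum / total
}

# Exhaustive optimum of the 2-cluster k-means objective over all
# 2-partitions of up to ~10 points.
brute_kmeans2_objective <- function(pts) {
  n <- nrow(pts)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    lab <- c(0L, as.integer(intToBits(mask))[seq_len(n - 1)]) + 1L
    obj <- 0
    for (g in 1:2) {
      m <- pts[lab == g, , drop = FALSE]
      if (nrow(m)) obj <- obj + sum(sweep(m, 2, colMeans(m))^2)
    }
    best <- min(best, obj)
  }
  best
}

# Direct evaluation of the window trend features from their defining sums,
# written without reusing the package's helpers.
direct_gamma0 <- function(x) {
  n <- length(x)
  s <- sqrt(sum((x - sum(x) / n)^2) / n)
  if (s == 0) return(0)
  (sum(x) / n - x[1]) / s
}
direct_gamma1 <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / n)
  if (s == 0) return(0)
  sum((x - m)^3) / n / s^3
}

# Stationary AR(1) series with given correlation time (seconds at dt = 1)
# and marginal SD, with burn-in.
ar1_series <- function(n, tau = 85, sd = 1, burn = 600) {
  phi <- exp(-1 / tau)
  eps <- stats::rnorm(n + burn, 0, sd * sqrt(1 - phi^2))
  x <- as.numeric(stats::filter(eps, phi, method = "recursive"))
  uniform_series(x[(burn + 1):(burn + n)])
}

# Four Gaussian blobs at (+-1.2, +-1.2).
blob_points <- function(n_per = 50, sd = 0.1) {
  centers <- rbind(c(1.2, 1.2), c(1.2, -1.2), c(-1.2, 1.2), c(-1.2, -1.2))
  pts <- do.call(rbind, lapply(1:4, function(g)
    matrix(stats::rnorm(2 * n_per, 0, sd), n_per, 2) +
      matrix(centers[g, ], n_per, 2, byrow = TRUE)))
  list(points = pts, labels = rep(1:4, each = n_per))
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# A small complete synthetic session fixture (shorter than the default hour
# so unit tests stay fast).
quick_session <- function(seed = 1, duration = 1440, segment_s = 240, ...) {
  plan <- synthetic_plan(
    segments = default_segments(duration, segment_s),
    duration = duration, seed = seed, ...)
  generate_session(plan)
}
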
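fake_features <- function(de, dh) {
  structure(data.frame(window_start_s = seq_along(de), width_s = 90,
                       delta_e = de, delta_hr = dh,
                       gamma0_e = de, gamma1_e = 0,
                       gamma0_hr = dh, gamma1_hr = 0),
            class = c("window_features", "data.frame"))
}

test_that("feature scaling reaches 99% coverage of the unit square", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    sc <- scale_features(fake_features(rnorm(500), rnorm(500)), alpha = 3)
    if (sc$scaling$coverage >= 0.99 && sc$scaling$alpha == 3) hits <- hits + 1
    expect_gte(sc$scaling$coverage, 0.99)
  }
  expect_gte(hits, 19)

  set.seed(1)
  sc2 <- scale_features(fake_features(rnorm(300), rnorm(300)))
  expect_lt(abs(mean(sc2$points[, 1])), 0.05)

  # heavy tails force alpha upward, coverage still >= 99%
  set.seed(2)
  sc3 <- scale_features(fake_features(rt(500, 3), rt(500, 3)), alpha = 3)
  expect_gt(sc3$scaling$alpha, 3)
  expect_gte(sc3$scaling$coverage, 0.99)

  expect_error(scale_features(fake_features(rep(1, 10), rnorm(10))),
               "zero SD")
  # unscaling inverts scaling
  set.seed(3)
  f <- fake_features(rnorm(100, 2, 1), rnorm(100, -1, 2))
  sc4 <- scale_features(f)
  back <- unscale_points(sc4$points, sc4$scaling)
  expect_equal(unname(back[, 1]), f$delta_e, tolerance = 1e-12)
  expect_equal(unname(back[, 2]), f$delta_hr, tolerance = 1e-12)
})

test_that("k-means converges to a fixed point with non-increasing objective", {
  set.seed(10)
  pts <- matrix(rnorm(200), 100, 2)
  m1 <- kmeans_dynamics(pts, 1, seed = 1)
  expect_equal(as.numeric(m1$centroids), colMeans(pts), tolerance = 1e-12)

  for (s in 1:10) {
    set.seed(s)
    pts <- matrix(rnorm(160), 80, 2)
    mod <- kmeans_dynamics(pts, 3, seed = s)
    expect_true(all(diff(mod$objective_trace) <= 1e-9))
    # fixed point: nearest-centroid reassignment changes nothing
    d2 <- outer(rowSums(pts^2), rep(1, 3)) - 2 * pts %*% t(mod$centroids) +
      outer(rep(1, 80), rowSums(mod$centroids^2))
    expect_identical(max.col(-d2, ties.method = "first"), mod$labels)
    # objective equals the summed squared distances of the final assignment
    expect_equal(mod$objective,
                 sum(d2[cbind(1:80, mod$labels)]), tolerance = 1e-9)
  }

  expect_error(kmeans_dynamics(matrix(rnorm(6), 3, 2), 4), "exceeds")
})

test_that("k-means recovers planted blobs and small-n optima", {
  set.seed(42)
  bl <- blob_points(50, 0.1)
  mod <- kmeans_dynamics(bl$points, 4, n_init = 10, seed = 7)
  expect_equal(adjusted_rand(mod$labels, bl$labels), 1.0)

  for (s in 1:10) {
    set.seed(s)
    pts <- matrix(rnorm(14), 7, 2)
    mod <- kmeans_dynamics(pts, 2, n_init = 50, seed = s)
    expect_equal(mod$objective, brute_kmeans2_objective(pts),
                 tolerance = 1e-9)
  }
})

test_that("silhouette values follow the defining equations", {
  sr <- silhouette_values(matrix(c(0, 1, 10, 11)), c("A", "A", "B", "B"))
  expect_equal(sr$s[1], (10.5 - 1) / 10.5, tolerance = 1e-12)
  expect_true(all(sr$s >= -1 & sr$s <= 1))

  # singleton cluster contributes 0
  sr2 <- silhouette_values(matrix(c(0, 1, 5)), c(1, 1, 2))
  expect_equal(sr2$s[3], 0)

  # random labels on one blob: mean silhouette near zero
  set.seed(31)
  pts <- matrix(rnorm(600), 300, 2)
  sr3 <- silhouette_values(pts, sample(1:3, 300, replace = TRUE))
  expect_lt(abs(sr3$mean), 0.1)

  expect_error(silhouette_values(matrix(rnorm(10)), rep(1, 10)), ">= 2")

  # equality with the brute-force double loop
  for (s in 1:10) {
    set.seed(s)
    n <- sample(10:60, 1)
    pts <- matrix(rnorm(2 * n), n, 2)
    labs <- sample(1:3, n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    expect_equal(silhouette_values(pts, labs)$s, brute_silhouette(pts, labs),
                 tolerance = 1e-12)
  }
})

test_that("silhouette-based k selection finds planted structure", {
  set.seed(42)
  bl <- blob_points(40, 0.1)
  sel <- select_k(bl$points, 2:10, seed = 3)
  expect_equal(sel$chosen_k, 4)

  two <- rbind(matrix(rnorm(80, 0, 0.1), 40, 2),
               matrix(rnorm(80, 3, 0.1), 40, 2))
  sel2 <- select_k(two, 2:8, seed = 3)
  expect_equal(sel2$chosen_k, 2)

  set.seed(17)
  flat <- matrix(runif(400), 200, 2)
  expect_warning(sel3 <- select_k(flat, 2:6, seed = 3), "weak")
  expect_lt(max(sel3$scores$mean_silhouette), 0.5)

  expect_warning(select_k(matrix(rnorm(12), 6, 2), 2:10, seed = 1),
                 "clipped")
})

test_that("sign labels map centroids to regime names", {
  mk_model <- function(raw_centroids, scaling) {
    scaled <- cbind(
      (raw_centroids[, 1] - scaling$mean_e) / (scaling$alpha * scaling$s_e),
      (raw_centroids[, 2] - scaling$mean_hr) / (scaling$alpha * scaling$s_h))
    structure(list(k = nrow(raw_centroids), centroids = scaled,
                   labels = seq_len(nrow(raw_centroids)), objective = 0,
                   objective_trace = 0, iterations = 1,
                   mean_silhouette = NA_real_, sign_labels = NULL),
              class = "cluster_model")
  }
  scaling <- structure(list(mean_e = 0, mean_hr = 0, s_e = 1, s_h = 1,
                            alpha = 3, coverage = 1),
                       class = "feature_scaling")
  cent <- rbind(c(-1.29, 1.13), c(1.30, -1.06), c(1.24, 1.16),
                c(-1.25, -1.20))
  mod <- assign_sign_labels(mk_model(cent, scaling), scaling)
  expect_equal(mod$sign_labels, c("-/+", "+/-", "+/+", "-/-"))

  dup <- rbind(c(1, 1), c(2, 2), c(-1, 1), c(1, -1))
  expect_error(assign_sign_labels(mk_model(dup, scaling), scaling),
               "not sign-separated")

  onaxis <- rbind(c(0, 1), c(1, -1), c(-1, 1), c(-1, -1))
  expect_warning(modz <- assign_sign_labels(mk_model(onaxis, scaling),
                                            scaling),
                 "sign\\(0\\)")
  expect_equal(modz$sign_labels[1], "+/+")
})
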
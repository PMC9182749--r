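test_that("regime frequencies count labels and sum to one", {
  s <- cluster_frequencies(c("-/+", "-/+", "-/-", "+/+"))
  expect_equal(s$freq_mp, 0.5)
  expect_equal(s$freq_mm, 0.25)
  expect_equal(s$freq_pp, 0.25)
  expect_equal(s$freq_pm, 0)

  s2 <- cluster_frequencies(rep("+/-", 7))
  expect_equal(s2$freq_pm, 1)
  expect_equal(s2$freq_pp + s2$freq_mp + s2$freq_mm, 0)

  set.seed(5)
  labs <- sample(c("+/+", "+/-", "-/+", "-/-"), 100, replace = TRUE)
  s3 <- cluster_frequencies(labs)
  expect_equal(s3$freq_pp + s3$freq_pm + s3$freq_mp + s3$freq_mm, 1,
               tolerance = 1e-12)
  # permutation equivariance: frequencies invariant to window order
  expect_equal(as.data.frame(cluster_frequencies(sample(labs)))[-(1:2)],
               as.data.frame(s3)[-(1:2)])

  expect_error(cluster_frequencies(character(0)), "no labelled")
  expect_error(cluster_frequencies("x/y"), "unknown")
})

test_that("non-overlapping subsets stride by the window width", {
  f <- data.frame(window_start_s = 0:90, width_s = 90)
  sub <- nonoverlapping_subset(f)
  expect_equal(sub$window_start_s, c(0, 90))

  one <- data.frame(window_start_s = 5, width_s = 90)
  expect_equal(nonoverlapping_subset(one)$window_start_s, 5)

  set.seed(6)
  starts <- sort(sample(0:2000, 300))
  f2 <- data.frame(window_start_s = starts, width_s = 90)
  sub2 <- nonoverlapping_subset(f2)
  expect_true(all(diff(sub2$window_start_s) >= 90))

  # gap-free grid: size formula floor((n_starts - 1)/width) + 1
  for (n in c(91, 180, 181, 300)) {
    f3 <- data.frame(window_start_s = 0:(n - 1), width_s = 90)
    expect_equal(nrow(nonoverlapping_subset(f3)),
                 floor((n - 1) / 90) + 1)
  }
})

test_that("section frequencies partition the session by window midpoint", {
  # all -/- windows in the first third
  s <- section_frequencies(rep("-/-", 20), seq(0, 200, length.out = 20),
                           90, 1000)
  expect_equal(s$freq_mm[s$section == "start"], 1)
  expect_equal(s$n_windows[s$section == "middle"], 0)
  expect_warning(
    section_frequencies(rep("-/-", 3), c(0, 10, 20), 90, 1000),
    "no windows")

  # boundary window assigned by its midpoint
  s2 <- section_frequencies(c("+/+", "-/-"), c(1000 / 3 - 46, 1000 / 3 - 44),
                            90, 1000)
  expect_equal(s2$n_windows, c(1L, 1L, 0L))

  # uniform labels: counts spread evenly across sections
  set.seed(12)
  labs <- sample(c("+/+", "-/-"), 300, replace = TRUE)
  starts <- runif(300, 0, 910)
  s3 <- section_frequencies(labs, starts, 90, 1000)
  counts <- table(factor(
    cut((starts + 45) / 1000, c(-Inf, 1 / 3, 2 / 3, Inf),
        labels = c("start", "middle", "end"), right = FALSE)))
  expect_gt(chisq.test(as.numeric(counts))$p.value, 0.05)

  # recomposition: total frequency is the window-weighted mean of sections
  s4 <- section_frequencies(labs, starts, 90, 1000)
  tot <- cluster_frequencies(labs)
  recomposed <- sum(s4$freq_pp * s4$n_windows) / sum(s4$n_windows)
  expect_equal(recomposed, tot$freq_pp, tolerance = 1e-12)
})

test_that("VO2max correlation recovers planted relations", {
  mk <- function(freqs, vo2) {
    do.call(rbind, lapply(seq_along(vo2), function(i)
      as.data.frame(cluster_frequencies(
        c(rep("-/+", freqs[i]), rep("-/-", 20 - freqs[i])),
        session_id = i, vo2max = vo2[i]))))
  }
  vo2 <- c(32, 34, 36, 38)
  rep1 <- correlate_vo2max(mk(c(4, 8, 12, 16), vo2))
  expect_equal(rep1$r[rep1$label == "-/+"], 1, tolerance = 1e-12)
  expect_equal(rep1$r[rep1$label == "-/-"], -1, tolerance = 1e-12)

  expect_error(correlate_vo2max(mk(c(4, 8), c(32, 34))), ">= 3")
  expect_warning(cw <- correlate_vo2max(mk(c(5, 5, 5, 5), vo2)),
                 "undefined")
  expect_true(is.na(cw$r[cw$label == "-/+"]))

  sm <- mk(c(4, 8, 12, 16), vo2)
  sm$vo2max[2] <- NA
  expect_warning(correlate_vo2max(sm), "excluded")

  # permuted VO2max destroys the correlation
  set.seed(30)
  freqs <- c(3, 5, 7, 9, 11, 13, 15, 17, 6, 10, 14, 18)
  vo2b <- seq(32, 38, length.out = 12)
  small_p <- 0
  for (b in 1:100) {
    perm <- suppressWarnings(correlate_vo2max(mk(freqs, sample(vo2b))))
    if (perm$p_value[perm$label == "-/+"] > 0.05) small_p <- small_p + 1
  }
  expect_gte(small_p, 90)
})

test_that("group tests gate on normality and adjust post-hoc p-values", {
  set.seed(44)
  base <- rnorm(30)
  same <- group_tests(rep(base, 3), rep(c("a", "b", "c"), each = 30))
  expect_gt(same$omnibus$p_value, 0.9)
  expect_true(all(same$posthoc$p_adj > 0.9))

  # well-separated groups detected essentially always
  hits <- 0
  for (b in 1:100) {
    set.seed(b)
    v <- c(rnorm(30), rnorm(30, 3))
    g <- rep(c("a", "b"), each = 30)
    r <- group_tests(v, g)
    if (r$omnibus$p_value < 0.05 && all(r$posthoc$p_adj < 0.05))
      hits <- hits + 1
  }
  expect_gte(hits, 99)

  # Bonferroni: adjusted p = min(1, m * raw)
  set.seed(2)
  v <- c(rnorm(20), rnorm(20, 0.5), rnorm(20, 1))
  r3 <- group_tests(v, rep(c("a", "b", "c"), each = 20))
  expect_equal(r3$posthoc$p_adj, pmin(1, 3 * r3$posthoc$p_raw))

  # non-normal data routed to Kruskal-Wallis
  set.seed(3)
  vexp <- c(rexp(40), rexp(40, 0.5))
  r4 <- group_tests(vexp, rep(c("a", "b"), each = 40))
  expect_false(r4$normal)
  expect_match(r4$omnibus$test, "Kruskal")

  # repeated-measures design uses the subject factor
  set.seed(4)
  subj <- rep(1:10, times = 3)
  sect <- rep(c("start", "middle", "end"), each = 10)
  val <- rnorm(30) + rep(c(0, 0.5, 1.5), each = 10) + rnorm(10)[subj]
  r5 <- group_tests(val, sect, design = "repeated", subject = subj)
  expect_match(r5$omnibus$test, "repeated")
  expect_lt(r5$omnibus$p_value, 0.05)
  expect_error(group_tests(val, sect, design = "repeated"), "subject")

  expect_error(group_tests(rep(1, 20), rep(c("a", "b"), each = 10)),
               "degenerate")
})

test_that("p-value stars follow the annotation legend", {
  expect_equal(p_stars(c(0.2, 0.03, 0.005, 5e-4, 5e-5)),
               c("ns", "*", "**", "***", "****"))
})
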
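test_that("exact enumeration reproduces hand-computed p-values", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$U, 0)
  expect_equal(rs$p_two_sided, 0.1)    # 2 * (1/20) over C(6,3) assignments
  expect_equal(rs$method, "exact_enumeration")

  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_two_sided, 1)
  expect_equal(same$method, "exact_with_ties")
})

test_that("swapping group labels mirrors U and preserves p", {
  set.seed(15)
  a <- rnorm(5)
  b <- rnorm(7, 1)
  r1 <- rank_sum_test(a, b)
  r2 <- rank_sum_test(b, a)
  expect_equal(r1$p_two_sided, r2$p_two_sided)
  expect_equal(r2$U, r1$n1 * r1$n2 - r1$U)
})

test_that("degenerate single-larva groups give bounded p, never an error", {
  r <- rank_sum_test(1, 2)
  expect_true(r$p_two_sided >= 0.5 && r$p_two_sided <= 1)
  r2 <- rank_sum_test(5, c(1, 2, 3))
  expect_true(r2$p_two_sided > 0 && r2$p_two_sided <= 1)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
  expect_error(rank_sum_test(c(1, NA), c(2, 3)), "finite")
})

test_that("enumeration p equals an independent full-permutation oracle", {
  set.seed(16)
  for (i in 1:100) {
    n1 <- sample(1:6, 1)
    n2 <- sample(1:6, 1)
    vals <- if (i %% 3 == 0) sample(1:4, n1 + n2, TRUE) else rnorm(n1 + n2)
    a <- vals[seq_len(n1)]
    b <- vals[-seq_len(n1)]
    expect_equal(rank_sum_test(a, b)$p_two_sided, oracle_ranksum_p(a, b))
  }
})

test_that("exact test agrees with wilcox.test in the tie-free case", {
  set.seed(17)
  for (i in 1:20) {
    a <- rnorm(6)
    b <- rnorm(6, 0.8)
    ours <- rank_sum_test(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large samples fall back to a tie-corrected normal approximation", {
  set.seed(18)
  a <- rnorm(20)
  b <- rnorm(20, 1)
  r <- rank_sum_test(a, b)
  expect_equal(r$method, "normal_approx")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(r$p_two_sided, ref$p.value, tolerance = 1e-6)
})

test_that("compare_groups reports per-experiment and pooled rows with flags", {
  set.seed(19)
  metrics <- do.call(rbind, lapply(c("1", "2"), function(e)
    data.frame(larva_id = paste0(e, "_", 1:12),
               group = rep(c("mock", "infected"), each = 6),
               experiment = e,
               total_distance_px = c(rnorm(6, 5000, 300),
                                     rnorm(6, 12000, 500)),
               median_speed_px_per_interval = c(rnorm(6, 1.8, 0.1),
                                                rnorm(6, 3.6, 0.2)),
               median_bout_duration_windows = c(rnorm(6, 4), rnorm(6, 8)),
               bout_count = rpois(12, 45))))
  res <- compare_groups(metrics)
  expect_equal(nrow(res), 12)          # 4 metrics x (2 experiments + pooled)
  expect_setequal(unique(res$experiment), c("1", "2", "pooled"))
  dist_rows <- res[res$metric == "total_distance_px", ]
  expect_true(all(dist_rows$sig_0.05))
  expect_error(compare_groups(metrics[, -4]), "missing metric")
  expect_error(compare_groups(transform(metrics, group = "one")),
               "two groups")
})

test_that("metrics with undefined entries are dropped from that comparison", {
  metrics <- data.frame(larva_id = 1:8,
                        group = rep(c("a", "b"), each = 4),
                        experiment = "1",
                        total_distance_px = c(1:4, 11:14),
                        median_speed_px_per_interval = c(NA, 2, 3, 4,
                                                         11:14),
                        median_bout_duration_windows = 1,
                        bout_count = 5)
  res <- compare_groups(metrics)
  sp <- res[res$metric == "median_speed_px_per_interval", ]
  expect_equal(sp$n1, 3)
  expect_equal(sp$n2, 4)
})
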
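test_that("rank-sum test matches exact enumeration on small samples", {
  # x = {1,2}, y = {3,4}: only one of the 6 assignments puts both smallest
  # ranks in x, so P(x below y) = 1/6
  ts <- rank_sum_test(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(ts$W, 3)
  expect_equal(ts$p.value, 1 / 6)
  expect_true(ts$exact)

  # identical samples: midranks make the test symmetric, p ~ 0.5
  ts2 <- rank_sum_test(c(5, 5, 5), c(5, 5, 5), alternative = "less")
  expect_gte(ts2$p.value, 0.5)
  expect_equal(ts2$W, 3 * 3.5)

  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("normal approximation agrees with exact enumeration at n = 8", {
  set.seed(1)
  x <- rnorm(8)
  y <- rnorm(8, mean = 0.8)
  exact <- rank_sum_test(x, y, "less")
  expect_true(exact$exact)
  # force the large-sample path by replicating into n = 24 samples
  x3 <- rep(x, 3) + rnorm(24, sd = 1e-9)
  y3 <- rep(y, 3) + rnorm(24, sd = 1e-9)
  approx <- rank_sum_test(x3, y3, "less")
  expect_false(approx$exact)
  # same data through the exact path at n = 8 vs stats::wilcox.test oracle
  or <- suppressWarnings(stats::wilcox.test(x, y, alternative = "less",
                                            exact = TRUE))
  expect_equal(exact$p.value, or$p.value, tolerance = 1e-12)
  # W relates to the Mann-Whitney U reported by wilcox.test
  expect_equal(exact$W, or$statistic[[1]] + 8 * 9 / 2)
})

test_that("large-sample rank-sum agrees with the wilcox.test oracle", {
  set.seed(7)
  x <- rnorm(30)
  y <- rnorm(30, 0.5)
  ours <- rank_sum_test(x, y, "less")
  or <- stats::wilcox.test(x, y, alternative = "less", exact = FALSE,
                           correct = TRUE)
  expect_equal(ours$p.value, or$p.value, tolerance = 1e-9)
  two <- rank_sum_test(x, y, "two.sided")
  or2 <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(two$p.value, or2$p.value, tolerance = 1e-9)
})

test_that("seed derivation is deterministic and label-independent", {
  a <- pitchcortex:::derive_seed(1L, "P5", 3L)
  b <- pitchcortex:::derive_seed(1L, "P5", 3L)
  expect_identical(a, b)
  expect_true(a >= 1 && a < 2^31)
  # different labels and runs give different streams
  expect_false(a == pitchcortex:::derive_seed(1L, "TT", 3L))
  expect_false(a == pitchcortex:::derive_seed(1L, "P5", 4L))
  expect_false(a == pitchcortex:::derive_seed(2L, "P5", 3L))
})

test_that("consonance sets follow the Helmholtz classification", {
  cs <- consonance_sets()
  expect_setequal(cs$consonant, c("P1", "M3", "P4", "P5", "P8"))
  expect_setequal(cs$dissonant, c("m2", "M2", "TT", "m7", "M7"))
  tab <- dyad_table()
  expect_equal(nrow(tab), 13)
  expect_true(all(tab$ratio_num / tab$ratio_den >= 1))
})

test_that("experiment results replay bit-identically from their seeds", {
  cfg <- test_config()
  ex1 <- run_irn_latency_sweep(delays = 8e-3, iterations = 16L, n_runs = 1L,
                               config = cfg, seed = 11L, noise_dur = 0.3,
                               pitch_dur = 0.45)
  ex2 <- run_irn_latency_sweep(delays = 8e-3, iterations = 16L, n_runs = 1L,
                               config = cfg, seed = 11L, noise_dur = 0.3,
                               pitch_dur = 0.45)
  expect_identical(ex1$runs$latency_ms, ex2$runs$latency_ms)
  expect_identical(ex1$runs$seed, ex2$runs$seed)
  # tidy/glance accessors
  expect_s3_class(tidy(ex1), "tbl_df")
  expect_equal(nrow(glance(ex1)), 1)
  expect_equal(glance(ex1)$se_latency_ms,
               glance(ex1)$sd_latency_ms / sqrt(glance(ex1)$n_decided))
})
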
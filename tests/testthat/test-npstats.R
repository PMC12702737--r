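test_that("Shapiro-Wilk gate routes Gaussian and grossly non-normal samples", {
  gaussian <- qnorm(ppoints(50))          # exact normal quantiles, W near 1
  g <- shapiro_wilk_gate(gaussian)
  expect_true(g$normal)
  expect_gt(g$statistic, 0.99)

  two_point <- c(rep(0, 40), rep(10, 10))
  expect_false(shapiro_wilk_gate(two_point)$normal)

  expect_error(shapiro_wilk_gate(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk_gate(rnorm(5001)), "5000")
})

test_that("Mann-Whitney U matches brute-force counting and exact enumeration", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$statistic, 0)
  expect_equal(mann_whitney_u(c(5), c(1, 2, 3, 4))$statistic, 0)

  tied <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tied$statistic, 4.5)
  expect_gt(tied$p_value, 0.95)

  set.seed(41)
  for (n in 3:6) {
    for (rep in 1:5) {
      pooled <- sample(seq_len(50), 2 * n)   # tie-free by construction
      x <- pooled[seq_len(n)]; y <- pooled[-seq_len(n)]
      res <- mann_whitney_u(x, y)
      expect_true(res$exact)
      expect_equal(res$statistic, min(u_brute(x, y), u_brute(y, x)))
      expect_equal(res$p_value, mwu_p_enumerated(x, y), tolerance = 1e-12)
    }
  }
  expect_error(mann_whitney_u(numeric(0), c(1)), "non-missing")
})

test_that("Kruskal-Wallis matches the rank-sum formula and the two-group rank test", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))$statistic, 0)

  # hand evaluation: ranks 1..6, group rank means 1.5/3.5/5.5,
  # H = 12/(6*7) * sum(n_i * (rbar_i - 3.5)^2) = 12 * 16 / 42 = 32/7
  h <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(h$statistic, 32 / 7, tolerance = 1e-12)
  expect_equal(h$df, 2)

  set.seed(17)
  x <- rnorm(12); y <- rnorm(12, 1)
  expect_equal(kruskal_wallis(list(x, y))$p_value,
               mann_whitney_u(x, y)$p_value, tolerance = 0.02)
  expect_error(kruskal_wallis(list(c(1, 2))), "two samples")
})

test_that("Spearman correlation reproduces the rank formula", {
  x <- c(2, 5, 9, 11)
  expect_equal(spearman_rho(x, x)$statistic, 1)
  expect_equal(spearman_rho(x, -x)$statistic, -1)

  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) with d = (1,-1,1,-1), sum d^2 = 4
  r <- spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$statistic, 0.6)
  expect_equal(r$p_value,
               cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3), method = "spearman",
                        exact = FALSE)$p.value)
  expect_error(spearman_rho(1:4, 1:5), "equal length")
})

test_that("Cliff's delta fast path equals the quadratic definition, ties included", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3))$effect_size, 0)
  expect_equal(cliffs_delta(c(4, 5), c(1, 2))$effect_size, 1)
  expect_equal(cliffs_delta(c(1, 2, 3, 4), c(2, 3))$effect_size, 0)

  set.seed(23)
  for (i in 1:60) {
    x <- sample(1:10, sample(1:50, 1), replace = TRUE)
    y <- sample(1:10, sample(1:50, 1), replace = TRUE)
    expect_identical(cliffs_delta(x, y)$effect_size, cliffs_delta_brute(x, y))
    expect_identical(cliffs_delta(x, y)$effect_size,
                     -cliffs_delta(y, x)$effect_size)
  }
})

test_that("percentile bootstrap is reproducible, degenerate on constants, and 1/sqrt(n)-concentrating", {
  const <- bootstrap_ci(rep(7, 25), mean, n_resamples = 200, seed = 3)
  expect_equal(const$ci_low, 7)
  expect_equal(const$ci_high, 7)
  expect_lte(const$ci_low, const$ci_high)

  set.seed(19); x <- rnorm(40)
  a <- bootstrap_ci(x, mean, n_resamples = 500, seed = 5)
  b <- bootstrap_ci(x, mean, n_resamples = 500, seed = 5)
  expect_identical(a$replicates, b$replicates)

  widths <- vapply(c(25, 100, 400), function(n) {
    set.seed(n)
    ci <- bootstrap_ci(rnorm(n), mean, n_resamples = 600, seed = 1)
    ci$ci_high - ci$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  for (ratio in widths[-3] / widths[-1])
    expect_true(ratio > 1.4 && ratio < 2.9)   # ~ sqrt(4) per 4x n

  expect_error(bootstrap_ci(numeric(0), mean), "non-empty")
  expect_error(bootstrap_ci(1:10, function(d) stop("boom")), "failed")
})

test_that("percentile interval agrees with an independent bootstrap implementation", {
  set.seed(27)
  x <- rexp(35)
  mine <- bootstrap_ci(x, mean, n_resamples = 4000, seed = 8)
  ref <- boot::boot.ci(boot::boot(x, function(d, i) mean(d[i]), R = 4000),
                       type = "perc")$percent
  expect_equal(mine$ci_low, ref[4], tolerance = 0.05)
  expect_equal(mine$ci_high, ref[5], tolerance = 0.05)
})

test_that("the battery wrapper runs every advertised test on a cohort", {
  cohort <- generate_cohort(default_generative_config(n_participants = 40L, seed = 2L))
  bat <- nonparametric_battery(cohort, n_resamples = 100, seed = 4)
  expect_named(bat$normality,
               c("theta_change", "gamma_change", "affective_shift",
                 "delta_positive", "delta_negative"))
  expect_length(bat$correlations, 4L)
  expect_s3_class(bat$band_comparison, "emodyn_test")
  expect_equal(bat$n_tests, 10L)
  expect_error(nonparametric_battery(cohort[, 1:3]), "missing columns")
})
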
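test_that("design matrix columns are exact products and squares of the raw predictors", {
  row <- build_design_matrix(data.frame(theta_change = 2, gamma_change = 3,
                                        affective_shift = 4))
  expect_equal(unname(row[1, ]), c(1, 2, 3, 4, 8, 9, 16))

  zero <- build_design_matrix(data.frame(theta_change = 0, gamma_change = 0,
                                         affective_shift = 0))
  expect_equal(unname(zero[1, ]), c(1, 0, 0, 0, 0, 0, 0))

  dup <- data.frame(theta_change = c(1, 1), gamma_change = c(2, 2),
                    affective_shift = c(3, 3))
  expect_equal(nrow(build_design_matrix(dup)), 2L)   # no deduplication

  expect_error(build_design_matrix(data.frame(theta_change = 1)),
               "gamma_change, affective_shift")
  expect_error(build_design_matrix(data.frame(theta_change = NA_real_,
                                              gamma_change = 1,
                                              affective_shift = 1)), "missing")
})

test_that("least squares recovers an identifiable surface exactly from noiseless data", {
  cfg <- scaled_identifiable_config(n = 100L, noise = 0)
  cohort <- generate_cohort(cfg)
  for (side in c("positive", "negative")) {
    fit <- fit_model(build_design_matrix(cohort),
                     cohort[[paste0("delta_", side)]], paste0("delta_", side))
    truth <- cfg[[paste0("coef_", side)]]
    expect_lt(max(abs(fit$coefficients / truth - 1)), 1e-6)
  }
})

test_that("degenerate fits are refused with informative errors", {
  cohort <- generate_cohort(scaled_identifiable_config(n = 30L, noise = 1))
  # constant outcome on an O(1)-scale cohort: everything but the intercept
  # vanishes (on tiny predictor scales the zero coefficients are amplified
  # by 1/scale, so closeness is meaningful on the solver scale instead)
  set.seed(33)
  unit_cohort <- data.frame(theta_change = rnorm(30), gamma_change = rnorm(30),
                            affective_shift = rnorm(30))
  const_fit <- fit_model(build_design_matrix(unit_cohort), rep(3.5, 30))
  expect_equal(const_fit$coefficients[["intercept"]], 3.5, tolerance = 1e-8)
  expect_lt(max(abs(const_fit$coefficients[-1])), 1e-8)
  const_ref <- fit_model(build_design_matrix(cohort), rep(3.5, 30))
  expect_lt(max(abs(const_ref$coefficients_std[-1])), 1e-12)

  expect_error(fit_model(build_design_matrix(cohort[1:5, ]), rnorm(5)),
               "at least 8 rows")
  flat <- cohort
  flat$affective_shift <- 2   # constant predictor: shift columns collapse
  expect_error(fit_model(build_design_matrix(flat), flat$delta_positive),
               "affective_shift|shift_sq")
})

test_that("original-scale and solver-scale fits agree on ill-conditioned cohorts", {
  # raw columns span ~1e-22 (gamma squared) to ~1e2 (shift squared)
  cohort <- generate_cohort(default_generative_config(n_participants = 200L,
                                                      seed = 3L))
  fit <- fit_model(build_design_matrix(cohort), cohort$delta_positive,
                   "delta_positive")
  X <- build_design_matrix(cohort)
  Z <- cbind(1, sweep(sweep(X[, -1], 2, fit$center), 2, fit$scale, `/`))
  pred_orig <- drop(X %*% fit$coefficients)
  pred_std <- drop(Z %*% fit$coefficients_std)
  expect_lt(max(abs(pred_orig - pred_std)) / max(abs(pred_std)), 1e-8)
  expect_equal(predict(fit, cohort), pred_orig)
})

test_that("in-sample fit quality is monotone over the nested model family", {
  cohort <- generate_cohort(default_generative_config(n_participants = 80L,
                                                      seed = 12L))
  r2 <- vapply(list(multimodal = c("intercept", "theta_change", "gamma_change",
                                   "affective_shift", "theta_x_shift",
                                   "gamma_sq", "shift_sq"),
                    eeg_only = c("intercept", "theta_change", "gamma_change",
                                 "gamma_sq"),
                    panas_only = c("intercept", "affective_shift", "shift_sq")),
               function(terms) insample_r2(cohort, "delta_positive", terms),
               numeric(1))
  expect_gte(r2[["multimodal"]], r2[["panas_only"]])
  expect_gte(r2[["multimodal"]], r2[["eeg_only"]])
  expect_gte(r2[["panas_only"]], 0)
})

test_that("bootstrapped coefficients: degenerate on noiseless data, deterministic, and powered for the shift effect", {
  noiseless <- generate_cohort(scaled_identifiable_config(n = 60L, noise = 0))
  tab <- bootstrap_coefficients(noiseless, "delta_negative",
                                n_resamples = 200, seed = 6)
  width <- tab$ci_high - tab$ci_low
  scale_ref <- pmax(abs(tab$estimate), 1)
  expect_true(all(width / scale_ref <= 1e-6))

  cohort <- generate_cohort(default_generative_config(seed = 30L))
  a <- bootstrap_coefficients(cohort, "delta_negative", n_resamples = 150, seed = 9)
  b <- bootstrap_coefficients(cohort, "delta_negative", n_resamples = 150, seed = 9)
  expect_identical(a, b)

  # at the published effect size the shift CI should exclude zero nearly always
  excluded <- vapply(1:60, function(r) {
    co <- generate_cohort(default_generative_config(seed = 1000L + r))
    ci <- bootstrap_coefficients(co, "delta_negative", n_resamples = 200,
                                 seed = r)
    ci$ci_high[ci$term == "affective_shift"] < 0 ||
      ci$ci_low[ci$term == "affective_shift"] > 0
  }, logical(1))
  expect_gte(mean(excluded), 0.9)
})

test_that("mediation recovers a constructed indirect path and stays null for orthogonal mediators", {
  set.seed(44)
  n <- 10000
  p <- rnorm(n)
  m <- 2 * p + rnorm(n)
  chain <- data.frame(theta_change = p, gamma_change = rnorm(n),
                      affective_shift = m,
                      delta_positive = rnorm(n),
                      delta_negative = 3 * m + 0.5 * p + rnorm(n))
  med <- mediation_indirect(chain, "theta_change", outcome = "delta_negative",
                            n_boot = 100, seed = 2)
  expect_equal(med$path_a, 2, tolerance = 0.05)
  expect_equal(med$path_b, 3, tolerance = 0.05)
  expect_equal(med$indirect, 6, tolerance = 0.2)
  expect_equal(med$indirect, med$path_a * med$path_b)

  null_covered <- vapply(1:20, function(r) {
    set.seed(500 + r)
    d <- data.frame(theta_change = rnorm(50), gamma_change = rnorm(50),
                    affective_shift = rnorm(50),      # orthogonal to predictor
                    delta_positive = rnorm(50), delta_negative = rnorm(50))
    ci <- mediation_indirect(d, "theta_change", outcome = "delta_negative",
                             n_boot = 200, seed = r)
    ci$ci_low <= 0 && ci$ci_high >= 0
  }, logical(1))
  expect_gte(mean(null_covered), 0.9)

  degenerate <- data.frame(theta_change = rnorm(20), gamma_change = rnorm(20),
                           affective_shift = 1, delta_positive = rnorm(20),
                           delta_negative = rnorm(20))
  expect_error(mediation_indirect(degenerate, "theta_change",
                                  outcome = "delta_negative"), "zero-variance")
})

test_that("cross-validated model comparison is deterministic and honest about pure noise", {
  cohort <- generate_cohort(default_generative_config(n_participants = 200L,
                                                      seed = 15L))
  cohort$delta_positive <- rnorm(200, sd = 4)   # outcome carries no signal
  cmp <- compare_models(cohort, repeats = 10, seed = 5)
  expect_true(all(cmp$table$r_squared <= 0.1))

  cmp2 <- compare_models(cohort, repeats = 10, seed = 5)
  expect_equal(cmp, cmp2)
  expect_setequal(cmp$table$model, c("multimodal", "eeg_only", "panas_only"))
  expect_error(compare_models(cohort[1:3, ], folds = 5), "folds")
})
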
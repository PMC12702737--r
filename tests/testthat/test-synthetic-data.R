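test_that("reference configuration carries the published coefficients and derived moments", {
  cfg <- default_generative_config()
  expect_equal(cfg$coef_negative[[4]], -3.96)
  expect_equal(cfg$coef_negative[[2]], 2.68e-11)
  expect_equal(cfg$coef_positive[[3]], 1.70e-12)
  expect_equal(cfg$coef_positive[[7]], 79.43)
  expect_equal(cfg$n_participants, 50L)
  # moments recomputed here from the printed interval bounds
  expect_equal(cfg$theta_sd, (7.30581e-11 + 3.09131e-12) / (2 * 1.96) * sqrt(50))
  expect_equal(cfg$gamma_sd, (3.06104e-12 - 5.51989e-13) / (2 * 1.96) * sqrt(50))
  expect_equal(cfg$shift_mean, 1.651578947 - (-3.925368421))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(generative_config(n_participants = 1), "n_participants")
  expect_error(generative_config(theta_sd = -1), "theta_sd")
  expect_error(generative_config(coef_positive = numeric(6)), "coef_positive")
  expect_error(generative_config(noise_sd_negative = c(1, 2)), "noise_sd_negative")
})

test_that("noiseless cohorts satisfy both outcome equations exactly", {
  cfg <- scaled_identifiable_config(n = 100L, noise = 0)
  cohort <- generate_cohort(cfg)
  terms <- cbind(1, cohort$theta_change, cohort$gamma_change,
                 cohort$affective_shift,
                 cohort$theta_change * cohort$affective_shift,
                 cohort$gamma_change^2, cohort$affective_shift^2)
  expect_equal(cohort$delta_positive, drop(terms %*% cfg$coef_positive),
               tolerance = 1e-9)
  expect_equal(cohort$delta_negative, drop(terms %*% cfg$coef_negative),
               tolerance = 1e-9)
  # record-level identities
  expect_equal(cohort$delta_positive, cohort$pa_post - cohort$pa_pre)
  expect_equal(cohort$delta_negative, cohort$na_post - cohort$na_pre)
})

test_that("identical configurations give bit-identical cohorts; seeds differentiate", {
  cfg <- default_generative_config(n_participants = 40L)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  other <- default_generative_config(n_participants = 40L, seed = 43L)
  expect_false(identical(generate_cohort(cfg)$theta_change,
                         generate_cohort(other)$theta_change))
})

test_that("enlarging the cohort leaves earlier participants untouched", {
  small <- generate_cohort(default_generative_config(n_participants = 30L))
  large <- generate_cohort(default_generative_config(n_participants = 60L))
  for (col in c("theta_change", "gamma_change", "affective_shift",
                "delta_positive", "delta_negative"))
    expect_identical(small[[col]], large[[col]][1:30], label = col)
})

test_that("generated predictor moments match the configuration at large n", {
  cfg <- default_generative_config(n_participants = 100000L, seed = 7L)
  cohort <- generate_cohort(cfg)
  se <- cfg$theta_sd / sqrt(cfg$n_participants)
  expect_lt(abs(mean(cohort$theta_change) - cfg$theta_mean), 3 * se)
  expect_lt(abs(sd(cohort$theta_change) / cfg$theta_sd - 1), 0.02)
  expect_lt(abs(sd(cohort$gamma_change) / cfg$gamma_sd - 1), 0.02)
  expect_lt(abs(sd(cohort$affective_shift) / cfg$shift_sd - 1), 0.02)
})

test_that("item-emitting cohorts have consistent items, scores and deltas", {
  cfg <- generative_config(
    n_participants = 40L,
    coef_positive = c(2, 0, 0, 0.3, 0, 0, 0),
    coef_negative = c(-3, 0, 0, -0.2, 0, 0, 0),
    shift_mean = 3, shift_sd = 6, noise_sd_positive = 2, noise_sd_negative = 2,
    emit_items = TRUE, seed = 5L)
  cohort <- generate_cohort(cfg)
  item_cols <- function(prefix, when) sprintf("%s%02d_%s", prefix, 1:10, when)
  for (spec in list(c("pa", "pre"), c("na", "pre"), c("pa", "post"), c("na", "post"))) {
    items <- as.matrix(cohort[, item_cols(spec[1], spec[2])])
    expect_true(all(items >= 1 & items <= 5))
    expect_equal(unname(rowSums(items)),
                 cohort[[paste(spec[1], spec[2], sep = "_")]])
  }
  expect_true(all(cohort$pa_post >= 10 & cohort$pa_post <= 50))
  expect_equal(cohort$delta_positive, cohort$pa_post - cohort$pa_pre)
  expect_true(is.numeric(attr(cohort, "n_clipped")))
})

test_that("derived shift mode computes the affective shift from PANAS score arithmetic", {
  cfg <- generative_config(n_participants = 50L,
                           coef_positive = c(1, 0, 0, 0.5, 0, 0, 0),
                           coef_negative = c(-1, 0, 0, -0.5, 0, 0, 0),
                           shift_mean = 4, shift_sd = 8,
                           noise_sd_positive = 0, noise_sd_negative = 0,
                           shift_mode = "derived", seed = 21L)
  cohort <- generate_cohort(cfg)
  expect_identical(attr(cohort, "shift_mode"), "derived")
  # shift distribution inherits the configured moments (loose sanity bounds)
  expect_lt(abs(mean(cohort$affective_shift) - 4), 4)
  # outcomes still satisfy the generative equation built on that shift
  expect_equal(cohort$delta_positive, 1 + 0.5 * cohort$affective_shift)
  expect_equal(cohort$delta_negative, -1 - 0.5 * cohort$affective_shift)
})

test_that("EEG pair generation scales band power by the configured multipliers", {
  pair_id <- generate_eeg_pair(channels = 8, duration = 6, seed = 2)
  expect_identical(pair_id$pre$samples, pair_id$post$samples)

  pair <- generate_eeg_pair(channels = 8, duration = 6,
                            theta_multiplier = 2, gamma_multiplier = 0.5, seed = 2)
  # pre recordings are invariant to the multipliers (shared components)
  expect_identical(pair$pre$samples, pair_id$pre$samples)
  expect_equal(dim(pair$pre$samples), c(8L, 6L * 128L))
  expect_identical(pair$pre$channel_labels, pair$post$channel_labels)

  expect_error(generate_eeg_pair(duration = 2), "duration")
  expect_error(generate_eeg_pair(theta_multiplier = 0), "positive")
  expect_error(generate_eeg_pair(fs = 64), "fs")
})
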
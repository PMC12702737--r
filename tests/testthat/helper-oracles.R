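# Independent oracles and shared fixtures. Everything here is deliberately
# naive (O(n^2) loops, exhaustive enumeration) so it cannot share a bug
# with the implementation paths it checks.

# Cliff's delta by the definition: double loop over all cross-pairs.
cliffs_delta_brute <- function(x, y) {
  wins <- 0L; losses <- 0L
  for (xi in x) for (yj in y) {
    if (xi > yj) wins <- wins + 1L
    if (xi < yj) losses <- losses + 1L
  }
  (wins - losses) / (length(x) * length(y))
}

# Mann-Whitney U (x side) by counting pairwise wins, ties at half weight.
u_brute <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Exact two-sided Mann-Whitney p by full enumeration of all group
# assignments of the pooled (tie-free) sample.
mwu_p_enumerated <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  splits <- utils::combn(n, nx)
  us <- apply(splits, 2L, function(idx) u_brute(pooled[idx], pooled[-idx]))
  u_obs <- u_brute(x, y)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Central finite-difference gradient of the payoff in standardized
# coordinates.
numeric_gradient <- function(point, model, h = 1e-6) {
  vapply(1:3, function(j) {
    e <- numeric(3); e[j] <- h
    (payoff(point + e, model) - payoff(point - e, model)) / (2 * h)
  }, numeric(1))
}

# A generative configuration keeping the study's raw predictor scales
# (1e-11 theta, 1e-12 gamma) but with coefficients chosen so every
# surface term contributes an O(1)..O(10) share of the outcome — i.e. a
# fully identifiable surface for exact-recovery checks.
scaled_identifiable_config <- function(n = 100L, noise = 0, seed = 11L) {
  generative_config(
    n_participants = n,
    coef_positive = c(1.5, 2.0e10, 2.0e11, -0.8, 5.0e8, 1.0e22, 0.05),
    coef_negative = c(-0.5, -1.5e10, 1.0e11, 0.6, -4.0e8, 2.0e22, -0.03),
    theta_mean = 2.7e-11, theta_sd = 1.37e-10,
    gamma_mean = 1.7e-12, gamma_sd = 4.5e-12,
    shift_mean = 5.6, shift_sd = 10.9,
    noise_sd_positive = noise, noise_sd_negative = noise,
    seed = seed)
}

# Ordinary in-sample OLS R^2 for a subset of design-matrix columns,
# via stats::lm on the raw columns (small, well-behaved test cohorts only).
insample_r2 <- function(cohort, outcome, terms) {
  X <- build_design_matrix(cohort)
  df <- as.data.frame(X[, setdiff(terms, "intercept"), drop = FALSE])
  df$.y <- cohort[[outcome]]
  summary(stats::lm(.y ~ ., data = df))$r.squared
}
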
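test_result <- function(method, statistic, p_value, effect_size = NA_real_,
                        n_per_group, extra = list()) {
  structure(c(list(method = method, statistic = unname(statistic),
                   p_value = unname(p_value), effect_size = effect_size,
                   n_per_group = n_per_group), extra),
            class = "emodyn_test")
}

#' @export
print.emodyn_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g", x$method, x$statistic, x$p_value))
  if (!is.na(x$effect_size)) cat(sprintf(", effect size = %.4g", x$effect_size))
  cat(" (n = ", paste(x$n_per_group, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

check_sample <- function(x, name, min_n = 1L) {
  if (length(x) < min_n || anyNA(x))
    stop(sprintf("'%s' must contain at least %d non-missing values", name, min_n),
         call. = FALSE)
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Runs the Shapiro-Wilk test and reports the routing flag used by the
#' analysis battery: when the flag is `FALSE` (p < 0.05) the distribution
#' deviates from normality and the pipeline uses the nonparametric tests.
#'
#' @param x Numeric sample, 3 <= n <= 5000.
#' @param alpha Gate level.
#' @return An `emodyn_test` with fields `method = "shapiro_wilk"`,
#'   `statistic` (W), `p_value`, and `normal` (the flag).
#' @export
shapiro_wilk_gate <- function(x, alpha = 0.05) {
  if (length(x) < 3L || length(x) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got n = ", length(x), call. = FALSE)
  check_sample(x, "x", 3L)
  sw <- stats::shapiro.test(x)
  test_result("shapiro_wilk", sw$statistic, sw$p.value,
              n_per_group = length(x),
              extra = list(normal = unname(sw$p.value >= alpha)))
}

# Rank-sum machinery shared by the Mann-Whitney statistic and the Cliff's
# delta fast path: U counts pairwise wins, ties at half weight (midranks).
u_statistics <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  c(ux = ux, uy = nx * ny - ux)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with midrank tie handling. The reported
#' statistic is `min(Ux, Uy)`. The p-value uses the exact distribution
#' when `nx * ny <= 400` and the data are tie-free, otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y Numeric samples.
#' @return An `emodyn_test`; `effect_size` carries Cliff's delta of
#'   `x` versus `y`, and `exact` records which p-value path was used.
#' @export
mann_whitney_u <- function(x, y) {
  check_sample(x, "x"); check_sample(y, "y")
  u <- u_statistics(x, y)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) * length(y) <= 400L) && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  test_result("mann_whitney_u", min(u), p,
              effect_size = cliffs_delta(x, y)$effect_size,
              n_per_group = c(length(x), length(y)),
              extra = list(exact = exact, u_x = unname(u["ux"]),
                           u_y = unname(u["uy"])))
}

#' Kruskal-Wallis H test
#'
#' Rank-based comparison of two or more groups, tie-corrected H statistic
#' with a chi-square reference (k - 1 degrees of freedom).
#'
#' @param groups List of two or more non-empty numeric samples.
#' @return An `emodyn_test`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("'groups' must be a list of at least two samples", call. = FALSE)
  for (i in seq_along(groups)) check_sample(groups[[i]], paste0("groups[[", i, "]]"))
  if (sum(lengths(groups)) < 3L)
    stop("need at least 3 observations in total", call. = FALSE)
  kw <- stats::kruskal.test(groups)
  test_result("kruskal_wallis", kw$statistic, kw$p.value,
              n_per_group = lengths(groups),
              extra = list(df = unname(kw$parameter)))
}

#' Spearman rank correlation
#'
#' Correlation of midranks, with a two-sided p-value from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Paired numeric samples of equal length >= 3.
#' @return An `emodyn_test` whose `statistic` and `effect_size` are rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  check_sample(x, "x", 3L); check_sample(y, "y", 3L)
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  if (is.na(rho))
    stop("rank correlation undefined (zero rank variance)", call. = FALSE)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  test_result("spearman", rho, p, effect_size = rho, n_per_group = n)
}

#' Cliff's delta ordinal effect size
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (nx * ny)`, in [-1, 1].
#' Computed via the rank identity `delta = (2 Ux - nx ny) / (nx ny)`
#' (O(n log n)); ties contribute half a win to each side and cancel
#' exactly, so the fast path agrees with the quadratic definition.
#'
#' @param x,y Numeric samples.
#' @return An `emodyn_test` with `statistic` and `effect_size` both delta.
#' @examples
#' cliffs_delta(c(4, 5), c(1, 2))$effect_size   # complete dominance: 1
#' @export
cliffs_delta <- function(x, y) {
  check_sample(x, "x"); check_sample(y, "y")
  nx <- length(x); ny <- length(y)
  u <- u_statistics(x, y)
  delta <- unname((u["ux"] - u["uy"]) / (nx * ny))
  test_result("cliffs_delta", delta, NA_real_, effect_size = delta,
              n_per_group = c(nx, ny))
}

#' Percentile bootstrap confidence interval
#'
#' Case resampling with replacement (row-level for tabular data), with the
#' interval taken from the empirical `alpha/2` and `1 - alpha/2` quantiles
#' of the resampled statistics. The point estimate is the statistic on the
#' original data. Resamples on which the statistic fails are counted;
#' more than 1% failures is an error.
#'
#' @param data Numeric vector, or data.frame/matrix resampled by rows.
#' @param statistic Function of one resample returning a single number.
#' @param n_resamples Number of bootstrap resamples (>= 1).
#' @param level Confidence level in (0, 1).
#' @param seed Integer seed; identical inputs give identical intervals.
#' @return List of class `bootstrap_result`: `estimate`, `ci_low`,
#'   `ci_high`, `level`, `n_resamples`, `n_failed`, `seed`,
#'   `method = "percentile"`, and the resampled `replicates`.
#' @examples
#' bootstrap_ci(rnorm(30), mean, n_resamples = 200, seed = 1)
#' @export
bootstrap_ci <- function(data, statistic, n_resamples = 1000L, level = 0.95,
                         seed = 42L) {
  tabular <- is.data.frame(data) || is.matrix(data)
  n <- if (tabular) nrow(data) else length(data)
  if (n < 1L) stop("'data' must be non-empty", call. = FALSE)
  if (n_resamples < 1L) stop("'n_resamples' must be >= 1", call. = FALSE)
  if (!(level > 0 && level < 1)) stop("'level' must lie in (0, 1)", call. = FALSE)
  take <- if (tabular) function(idx) data[idx, , drop = FALSE]
          else function(idx) data[idx]
  estimate <- tryCatch(statistic(data), error = function(e)
    stop("statistic failed on the original data: ", conditionMessage(e),
         call. = FALSE))
  replicates <- local_seed(as.integer(seed) %% .Machine$integer.max, {
    vapply(seq_len(n_resamples), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(as.numeric(statistic(take(idx)))[[1]],
               error = function(e) NA_real_)
    }, numeric(1))
  })
  n_failed <- sum(is.na(replicates))
  if (n_failed > 0.01 * n_resamples)
    stop(sprintf("statistic failed on %d of %d bootstrap resamples",
                 n_failed, n_resamples), call. = FALSE)
  alpha <- 1 - level
  qs <- stats::quantile(replicates, c(alpha / 2, 1 - alpha / 2),
                        na.rm = TRUE, names = FALSE)
  structure(list(estimate = unname(estimate), ci_low = qs[1L], ci_high = qs[2L],
                 level = level, n_resamples = as.integer(n_resamples),
                 n_failed = n_failed, seed = as.integer(seed),
                 method = "percentile", replicates = replicates),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("percentile bootstrap (%d resamples, seed %d): %.6g, %g%% CI [%.6g, %.6g]\n",
              x$n_resamples, x$seed, x$estimate, 100 * x$level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Nonparametric battery over a cohort
#'
#' Convenience wrapper running the full battery on a cohort table:
#' Shapiro-Wilk gates for each predictor and outcome, Spearman
#' correlations of each EEG change score with each outcome, a
#' Kruskal-Wallis comparison of (absolute) band-change contributions, and
#' percentile bootstrap intervals for the mean of each key variable.
#'
#' @param cohort Cohort `data.frame` (see [generate_cohort()]).
#' @param n_resamples,level,seed Bootstrap settings.
#' @return Nested list with elements `normality`, `correlations`,
#'   `band_comparison`, `bootstrap_means`, and `n_tests`.
#' @export
nonparametric_battery <- function(cohort, n_resamples = 1000L, level = 0.95,
                                  seed = 42L) {
  vars <- c("theta_change", "gamma_change", "affective_shift",
            "delta_positive", "delta_negative")
  missing_cols <- setdiff(vars, names(cohort))
  if (length(missing_cols) > 0L)
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  normality <- lapply(stats::setNames(vars, vars), function(v)
    shapiro_wilk_gate(cohort[[v]]))
  pairs <- expand.grid(predictor = c("theta_change", "gamma_change"),
                       outcome = c("delta_positive", "delta_negative"),
                       stringsAsFactors = FALSE)
  correlations <- lapply(seq_len(nrow(pairs)), function(i)
    c(pairs[i, ], list(test = spearman_rho(cohort[[pairs$predictor[i]]],
                                           cohort[[pairs$outcome[i]]]))))
  band_comparison <- kruskal_wallis(list(
    theta = abs(cohort$theta_change) / stats::sd(cohort$theta_change),
    gamma = abs(cohort$gamma_change) / stats::sd(cohort$gamma_change)))
  bootstrap_means <- lapply(stats::setNames(vars, vars), function(v)
    bootstrap_ci(cohort[[v]], mean, n_resamples = n_resamples,
                 level = level, seed = seed))
  list(normality = normality, correlations = correlations,
       band_comparison = band_comparison, bootstrap_means = bootstrap_means,
       n_tests = length(normality) + length(correlations) + 1L)
}
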
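PREDICTOR_COLS <- c("theta_change", "gamma_change", "affective_shift")

#' Build the quadratic/interaction design matrix
#'
#' Columns, in fixed order: intercept, theta change, gamma change,
#' affective shift, theta-by-shift interaction, gamma squared, shift
#' squared. Derived columns are computed from the raw (unstandardized)
#' predictors; the per-column centers and scales that the solver uses
#' internally are recorded as attributes, never baked into the stored
#' features.
#'
#' @param cohort `data.frame` containing `theta_change`, `gamma_change`,
#'   `affective_shift` with no missing values.
#' @return A numeric matrix of class `emodyn_design` with attributes
#'   `center` and `scale` (length 6, one per non-intercept column).
#' @examples
#' build_design_matrix(data.frame(theta_change = 2, gamma_change = 3,
#'                                affective_shift = 4))[1, ]
#' @export
build_design_matrix <- function(cohort) {
  missing_cols <- setdiff(PREDICTOR_COLS, names(cohort))
  if (length(missing_cols) > 0L)
    stop("cohort is missing predictor columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in PREDICTOR_COLS)
    if (anyNA(cohort[[col]]) || !all(is.finite(cohort[[col]])))
      stop("predictor column '", col, "' contains missing or non-finite values",
           call. = FALSE)
  X <- surface_terms(cohort$theta_change, cohort$gamma_change,
                     cohort$affective_shift)
  ctr <- colMeans(X[, -1L, drop = FALSE])
  scl <- apply(X[, -1L, drop = FALSE], 2L, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1   # constants flagged at fit time instead
  attr(X, "center") <- ctr
  attr(X, "scale") <- scl
  class(X) <- c("emodyn_design", class(X))
  X
}

#' Fit one affect-change response surface by least squares
#'
#' Ordinary least squares on internally centered and scaled columns, with
#' the coefficients mapped back to the original predictor scale exactly.
#' Standardizing inside the solver keeps the normal equations
#' well-conditioned even though the raw columns span ~20 orders of
#' magnitude (band-power changes near 1e-11, their squares near 1e-22,
#' PANAS shifts near 1e1); the back-transformation is linear, so no
#' approximation is introduced. Regularization is deliberately not used:
#' coefficients stay directly interpretable.
#'
#' @param design An `emodyn_design` from [build_design_matrix()].
#' @param outcome Numeric outcome vector (one per design row).
#' @param outcome_name Label stored in the result (e.g.
#'   `"delta_negative"`).
#' @return Object of class `emodyn_fit`: `coefficients` (named, original
#'   scale), `coefficients_std` (solver scale), `center`, `scale`,
#'   `residual_sd`, `r_squared`, `condition_number`, `n`, `outcome`.
#' @export
fit_model <- function(design, outcome, outcome_name = "outcome") {
  if (!inherits(design, "emodyn_design"))
    design <- build_design_matrix(design)
  n <- nrow(design)
  p <- ncol(design)
  if (length(outcome) != n)
    stop("'outcome' length must equal the number of design rows", call. = FALSE)
  if (anyNA(outcome) || !all(is.finite(outcome)))
    stop("'outcome' contains missing or non-finite values", call. = FALSE)
  if (n < p + 1L)
    stop(sprintf("need at least %d rows to fit %d coefficients, got %d",
                 p + 1L, p, n), call. = FALSE)
  ctr <- attr(design, "center"); scl <- attr(design, "scale")
  Z <- cbind(1, sweep(sweep(design[, -1L, drop = FALSE], 2L, ctr), 2L, scl, `/`))
  colnames(Z) <- colnames(design)
  qrz <- qr(Z)
  if (qrz$rank < p) {
    dropped <- colnames(Z)[qrz$pivot[(qrz$rank + 1L):p]]
    stop("rank-deficient design; offending columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(Z, outcome)
  bz <- fit$coefficients
  beta <- c(bz[1L] - sum(bz[-1L] * ctr / scl), bz[-1L] / scl)
  names(beta) <- colnames(design)
  resid <- fit$residuals
  sst <- sum((outcome - mean(outcome))^2)
  structure(list(
    outcome = outcome_name,
    coefficients = beta,
    coefficients_std = stats::setNames(bz, colnames(design)),
    center = ctr, scale = scl,
    residual_sd = sqrt(sum(resid^2) / max(1L, n - p)),
    r_squared = if (sst > 0) 1 - sum(resid^2) / sst else NA_real_,
    condition_number = kappa(Z, exact = TRUE),
    n = n
  ), class = "emodyn_fit")
}

#' @export
print.emodyn_fit <- function(x, ...) {
  cat(sprintf("Response-surface fit for %s (n = %d, R^2 = %.4f, residual sd = %.4g)\n",
              x$outcome, x$n, x$r_squared, x$residual_sd))
  print(signif(x$coefficients, 6))
  invisible(x)
}

#' Predict from a fitted response surface
#'
#' @param object An `emodyn_fit`.
#' @param newdata Cohort `data.frame` with the three predictor columns.
#' @param ... Unused.
#' @return Numeric predictions on the outcome (PANAS-point) scale.
#' @export
predict.emodyn_fit <- function(object, newdata, ...) {
  X <- build_design_matrix(newdata)
  drop(X %*% object$coefficients)
}

# Fit the named outcome of a cohort; shared by the bootstrap and CV paths.
fit_cohort_outcome <- function(cohort, outcome) {
  outcome <- match.arg(outcome, c("delta_positive", "delta_negative"))
  if (!outcome %in% names(cohort))
    stop("cohort is missing outcome column '", outcome, "'", call. = FALSE)
  fit_model(build_design_matrix(cohort), cohort[[outcome]], outcome)
}

#' Bootstrap the regression coefficients
#'
#' Participant-level case resampling: each of `n_resamples` resamples
#' redraws whole cohort rows with replacement, rebuilds the design matrix
#' from the resampled raw predictors, refits, and records all seven
#' original-scale coefficients. Percentile confidence intervals are taken
#' per coefficient.
#'
#' @param cohort Cohort `data.frame`.
#' @param outcome `"delta_positive"` or `"delta_negative"`.
#' @param n_resamples,level,seed Bootstrap settings (see [bootstrap_ci()]).
#' @return `data.frame` of class `emodyn_boot` with one row per
#'   coefficient: `term`, `estimate`, `ci_low`, `ci_high`, plus the
#'   settings as attributes.
#' @export
bootstrap_coefficients <- function(cohort, outcome, n_resamples = 1000L,
                                   level = 0.95, seed = 42L) {
  outcome <- match.arg(outcome, c("delta_positive", "delta_negative"))
  full_fit <- fit_cohort_outcome(cohort, outcome)
  n <- nrow(cohort)
  reps <- local_seed(as.integer(seed) %% .Machine$integer.max, {
    out <- matrix(NA_real_, n_resamples, 7L,
                  dimnames = list(NULL, COEF_NAMES))
    for (b in seq_len(n_resamples)) {
      idx <- sample.int(n, n, replace = TRUE)
      out[b, ] <- tryCatch(
        fit_cohort_outcome(cohort[idx, , drop = FALSE], outcome)$coefficients,
        error = function(e) rep(NA_real_, 7L))
    }
    out
  })
  n_failed <- sum(!stats::complete.cases(reps))
  if (n_failed > 0.01 * n_resamples)
    stop(sprintf("model fit failed on %d of %d bootstrap resamples",
                 n_failed, n_resamples), call. = FALSE)
  alpha <- 1 - level
  qs <- apply(reps, 2L, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2),
              na.rm = TRUE)
  res <- data.frame(term = COEF_NAMES,
                    estimate = unname(full_fit$coefficients),
                    ci_low = qs[1L, ], ci_high = qs[2L, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "outcome") <- outcome
  attr(res, "level") <- level
  attr(res, "n_resamples") <- as.integer(n_resamples)
  attr(res, "n_failed") <- n_failed
  attr(res, "seed") <- as.integer(seed)
  attr(res, "method") <- "percentile"
  class(res) <- c("emodyn_boot", class(res))
  res
}

#' Exploratory mediation through the affective shift
#'
#' Product-of-coefficients mediation: path a regresses the mediator on the
#' predictor, path b regresses the outcome on mediator plus predictor, and
#' the indirect effect a*b gets a percentile bootstrap interval over
#' participant-level case resamples. Exploratory by construction — the
#' mediator is built from the same instrument as the outcomes, and that
#' circularity is preserved, not corrected.
#'
#' @param cohort Cohort `data.frame`.
#' @param predictor `"theta_change"` or `"gamma_change"`.
#' @param mediator Mediator column (default `"affective_shift"`).
#' @param outcome `"delta_positive"` or `"delta_negative"`.
#' @param n_boot,level,seed Bootstrap settings.
#' @return List of class `emodyn_mediation`: `path_a`, `path_b`,
#'   `indirect`, `direct`, `ci_low`, `ci_high`, settings.
#' @export
mediation_indirect <- function(cohort, predictor = c("theta_change", "gamma_change"),
                               mediator = "affective_shift", outcome,
                               n_boot = 1000L, level = 0.95, seed = 42L) {
  predictor <- match.arg(predictor)
  outcome <- match.arg(outcome, c("delta_positive", "delta_negative"))
  for (col in c(predictor, mediator, outcome))
    if (!col %in% names(cohort))
      stop("cohort is missing column '", col, "'", call. = FALSE)
  paths <- function(d) {
    if (stats::sd(d[[mediator]]) == 0 || stats::sd(d[[predictor]]) == 0)
      stop("zero-variance mediator or predictor", call. = FALSE)
    a <- stats::coef(stats::lm(d[[mediator]] ~ d[[predictor]]))[[2L]]
    fit_b <- stats::lm(d[[outcome]] ~ d[[mediator]] + d[[predictor]])
    c(a = a, b = stats::coef(fit_b)[[2L]], direct = stats::coef(fit_b)[[3L]])
  }
  est <- paths(cohort)
  boot <- bootstrap_ci(cohort, function(d) { p <- paths(d); unname(p["a"] * p["b"]) },
                       n_resamples = n_boot, level = level, seed = seed)
  structure(list(predictor = predictor, mediator = mediator, outcome = outcome,
                 path_a = unname(est["a"]), path_b = unname(est["b"]),
                 indirect = unname(est["a"] * est["b"]),
                 direct = unname(est["direct"]),
                 ci_low = boot$ci_low, ci_high = boot$ci_high,
                 level = level, n_resamples = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "emodyn_mediation")
}

# Term sets for the three competing predictor models. Each unimodal model
# keeps its own nonlinear terms from the full equation.
MODEL_TERMS <- list(
  multimodal = COEF_NAMES,
  eeg_only = c("intercept", "theta_change", "gamma_change", "gamma_sq"),
  panas_only = c("intercept", "affective_shift", "shift_sq")
)

# Out-of-fold predictions for one term subset under given fold assignments.
cv_predictions <- function(X, y, term_set, fold_id) {
  pred <- rep(NA_real_, length(y))
  for (k in sort(unique(fold_id))) {
    test <- fold_id == k
    Xtr <- X[!test, term_set, drop = FALSE]
    ctr <- colMeans(Xtr[, -1L, drop = FALSE])
    scl <- apply(Xtr[, -1L, drop = FALSE], 2L, stats::sd)
    scl[scl == 0 | is.na(scl)] <- 1
    Ztr <- cbind(1, sweep(sweep(Xtr[, -1L, drop = FALSE], 2L, ctr), 2L, scl, `/`))
    bz <- stats::lm.fit(Ztr, y[!test])$coefficients
    Xte <- X[test, term_set, drop = FALSE]
    Zte <- cbind(1, sweep(sweep(Xte[, -1L, drop = FALSE], 2L, ctr), 2L, scl, `/`))
    pred[test] <- drop(Zte %*% bz)
  }
  pred
}

#' Compare multimodal and unimodal predictor models
#'
#' Repeated k-fold cross-validation of three nested models of the same
#' outcome: `multimodal` (all seven response-surface terms), `eeg_only`
#' (theta, gamma, gamma squared) and `panas_only` (shift, shift squared).
#' Within each repeat all three models share one random fold assignment;
#' out-of-fold predictions are pooled per repeat, RMSE and R-squared are
#' computed on the pooled predictions, and means are taken over repeats.
#'
#' @param cohort Cohort `data.frame`.
#' @param outcome Outcome column (default `"delta_positive"`).
#' @param folds Number of folds (n >= folds required).
#' @param repeats Number of independent fold assignments.
#' @param seed Integer seed.
#' @return Object of class `emodyn_comparison`: `table` (one row per
#'   model: `model`, `rmse`, `r_squared`), `delta_r2`
#'   (multimodal minus panas_only mean R-squared), settings.
#' @export
compare_models <- function(cohort, outcome = "delta_positive", folds = 5L,
                           repeats = 20L, seed = 42L) {
  outcome <- match.arg(outcome, c("delta_positive", "delta_negative"))
  n <- nrow(cohort)
  if (n < folds)
    stop(sprintf("need at least as many rows (%d) as folds (%d)", n, folds),
         call. = FALSE)
  X <- build_design_matrix(cohort)
  y <- cohort[[outcome]]
  model_names <- names(MODEL_TERMS)
  rmse <- matrix(NA_real_, repeats, length(model_names),
                 dimnames = list(NULL, model_names))
  r2 <- rmse
  local_seed(as.integer(seed) %% .Machine$integer.max, {
    for (r in seq_len(repeats)) {
      fold_id <- sample(rep_len(seq_len(folds), n))
      for (m in model_names) {
        pred <- cv_predictions(X, y, MODEL_TERMS[[m]], fold_id)
        rmse[r, m] <- sqrt(mean((y - pred)^2))
        r2[r, m] <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
      }
    }
  })
  tab <- data.frame(model = model_names,
                    rmse = colMeans(rmse),
                    r_squared = colMeans(r2),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab,
                 delta_r2 = tab$r_squared[tab$model == "multimodal"] -
                   tab$r_squared[tab$model == "panas_only"],
                 outcome = outcome, folds = as.integer(folds),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "emodyn_comparison")
}

#' @export
print.emodyn_comparison <- function(x, ...) {
  cat(sprintf("Model comparison for %s (%d-fold CV x %d repeats, seed %d)\n",
              x$outcome, x$folds, x$repeats, x$seed))
  print(transform(x$table, rmse = signif(rmse, 6),
                  r_squared = signif(r_squared, 6)), row.names = FALSE)
  cat(sprintf("delta R^2 (multimodal - panas_only): %.4g\n", x$delta_r2))
  invisible(x)
}
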
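# Coefficient order shared by every response-surface consumer in the package.
# (intercept, theta, gamma, shift, theta x shift, gamma^2, shift^2)
COEF_NAMES <- c("intercept", "theta_change", "gamma_change", "affective_shift",
                "theta_x_shift", "gamma_sq", "shift_sq")

#' Generative configuration for synthetic cohorts
#'
#' Describes the data-generating process behind [generate_cohort()]: two
#' 7-coefficient response surfaces (one per affect outcome), Gaussian
#' predictor distributions for the EEG change scores and the affective
#' shift, and independent Gaussian outcome noise.
#'
#' The two outcome equations share one functional form,
#' \deqn{\Delta E = \beta_0 + \beta_1\Delta\theta + \beta_2\Delta\gamma +
#'   \beta_3 AS + \beta_4(\Delta\theta \cdot AS) + \beta_5\Delta\gamma^2 +
#'   \beta_6 AS^2 + \varepsilon,}
#' where \eqn{\Delta\theta}/\eqn{\Delta\gamma} are raw pre-to-post band-power
#' differences (power units, typically 1e-11 / 1e-12 scale) and \eqn{AS} is
#' the affective shift in PANAS points.
#'
#' @param n_participants Cohort size (>= 2).
#' @param coef_positive,coef_negative Numeric length-7 coefficient vectors in
#'   the fixed order `intercept, theta, gamma, shift, theta_x_shift,
#'   gamma_sq, shift_sq`, for the positive- and negative-affect outcome
#'   equations respectively.
#' @param theta_mean,theta_sd Moments of the theta change-score distribution
#'   (band power units, ~1e-11 scale).
#' @param gamma_mean,gamma_sd Moments of the gamma change-score distribution
#'   (~1e-12 scale).
#' @param shift_mean,shift_sd Moments of the affective-shift distribution
#'   (PANAS points).
#' @param noise_sd_positive,noise_sd_negative Outcome noise standard
#'   deviations (PANAS points, >= 0).
#' @param shift_mode `"latent"` draws the affective shift directly from its
#'   configured distribution; `"derived"` draws PANAS pre/post scores first
#'   and computes the shift from them (see [generate_cohort()]).
#' @param emit_items If `TRUE`, back-fill 20 Likert items per administration
#'   consistent with each subscale score (scores are then rounded and
#'   clipped to the legal 10--50 range, with clipping counted).
#' @param seed Integer seed; identical configurations (including seed)
#'   produce bit-identical cohorts.
#' @return An object of class `generative_config` (a validated list).
#' @seealso [default_generative_config()], [generate_cohort()]
#' @export
generative_config <- function(n_participants = 50,
                              coef_positive = numeric(7),
                              coef_negative = numeric(7),
                              theta_mean = 0, theta_sd = 1e-11,
                              gamma_mean = 0, gamma_sd = 1e-12,
                              shift_mean = 0, shift_sd = 5,
                              noise_sd_positive = 4,
                              noise_sd_negative = 4,
                              shift_mode = c("latent", "derived"),
                              emit_items = FALSE,
                              seed = 42L) {
  shift_mode <- match.arg(shift_mode)
  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    coef_positive = as.numeric(coef_positive),
    coef_negative = as.numeric(coef_negative),
    theta_mean = theta_mean, theta_sd = theta_sd,
    gamma_mean = gamma_mean, gamma_sd = gamma_sd,
    shift_mean = shift_mean, shift_sd = shift_sd,
    noise_sd_positive = noise_sd_positive,
    noise_sd_negative = noise_sd_negative,
    shift_mode = shift_mode,
    emit_items = isTRUE(emit_items),
    seed = as.integer(seed)
  ), class = "generative_config")
  validate_generative_config(cfg)
  cfg
}

validate_generative_config <- function(cfg) {
  stopifnot(inherits(cfg, "generative_config"))
  if (is.na(cfg$n_participants) || cfg$n_participants < 2L)
    stop("invalid generative config: 'n_participants' must be >= 2", call. = FALSE)
  for (nm in c("coef_positive", "coef_negative")) {
    v <- cfg[[nm]]
    if (length(v) != 7L || anyNA(v) || !all(is.finite(v)))
      stop(sprintf("invalid generative config: '%s' must be 7 finite coefficients", nm),
           call. = FALSE)
  }
  for (nm in c("theta_sd", "gamma_sd", "shift_sd",
               "noise_sd_positive", "noise_sd_negative")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("invalid generative config: '%s' must be a single sd >= 0", nm),
           call. = FALSE)
  }
  for (nm in c("theta_mean", "gamma_mean", "shift_mean")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("invalid generative config: '%s' must be a single finite number", nm),
           call. = FALSE)
  }
  if (is.na(cfg$seed))
    stop("invalid generative config: 'seed' must be an integer", call. = FALSE)
  invisible(cfg)
}

#' Reference generative configuration
#'
#' The configuration used throughout the package as the study's reference
#' condition: 50 participants, the published fitted coefficients of the two
#' affect-change equations taken as generative truth, and predictor moments
#' recovered from published bootstrap confidence intervals
#' (SE = (hi - lo) / (2 * 1.96), SD = SE * sqrt(50)).
#'
#' The negative-affect equation carries the theta main effect and the
#' theta-by-shift interaction (cognitive-control pathway); the
#' positive-affect equation carries the gamma main effect, the gamma
#' quadratic, and the shift quadratic (arousal pathway). Outcome noise
#' defaults to 4 PANAS points per equation.
#'
#' @param ... Overrides passed on to [generative_config()] (e.g.
#'   `n_participants`, `seed`, `noise_sd_positive`).
#' @return A `generative_config`.
#' @examples
#' cfg <- default_generative_config()
#' cfg$coef_negative[[4]]   # shift coefficient, negative-affect equation
#' @export
default_generative_config <- function(...) {
  half_width <- function(lo, hi) (hi - lo) / (2 * 1.96)
  n_ref <- 50
  theta_mean <- 2.67218e-11
  theta_sd <- half_width(-3.09131e-12, 7.30581e-11) * sqrt(n_ref)
  gamma_mean <- 1.66029e-12
  gamma_sd <- half_width(5.51989e-13, 3.06104e-12) * sqrt(n_ref)
  dp_mean <- 1.651578947
  dp_sd <- half_width(-0.631578947, 4.052631579) * sqrt(n_ref)
  dn_mean <- -3.925368421
  dn_sd <- half_width(-5.894736842, -2.052631579) * sqrt(n_ref)
  # net affective shift = delta_positive - delta_negative; sds combined in
  # quadrature (pre/post subscale changes treated as independent)
  defaults <- list(
    n_participants = 50L,
    coef_negative = c(0, 2.68e-11, 0, -3.96, 1.77e-10, 0, 0),
    coef_positive = c(0, 0, 1.70e-12, 1.69, 0, 1.03e-23, 79.43),
    theta_mean = theta_mean, theta_sd = theta_sd,
    gamma_mean = gamma_mean, gamma_sd = gamma_sd,
    shift_mean = dp_mean - dn_mean,
    shift_sd = sqrt(dp_sd^2 + dn_sd^2),
    noise_sd_positive = 4.0,
    noise_sd_negative = 4.0,
    seed = 42L
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(generative_config, defaults)
}

#' @export
print.generative_config <- function(x, ...) {
  cat("Generative configuration (", x$n_participants, " participants, seed ",
      x$seed, ")\n", sep = "")
  cat("  shift_mode:", x$shift_mode, if (x$emit_items) "(item-level)" else "", "\n")
  coef_fmt <- function(v) paste(sprintf("%.4g", v), collapse = ", ")
  cat("  coef_positive: ", coef_fmt(x$coef_positive), "\n", sep = "")
  cat("  coef_negative: ", coef_fmt(x$coef_negative), "\n", sep = "")
  cat(sprintf("  theta ~ N(%.4g, %.4g), gamma ~ N(%.4g, %.4g), shift ~ N(%.4g, %.4g)\n",
              x$theta_mean, x$theta_sd, x$gamma_mean, x$gamma_sd,
              x$shift_mean, x$shift_sd))
  cat(sprintf("  noise sd: positive %.3g, negative %.3g (PANAS points)\n",
              x$noise_sd_positive, x$noise_sd_negative))
  invisible(x)
}

#' Write or read a generative configuration
#'
#' Plain-text (YAML) serialization so a cohort can be regenerated exactly
#' from its stored configuration.
#'
#' @param config A `generative_config`.
#' @param path File path.
#' @return `read_generative_config()` returns a `generative_config`;
#'   `write_generative_config()` returns `path` invisibly.
#' @export
write_generative_config <- function(config, path) {
  validate_generative_config(config)
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}

#' @rdname write_generative_config
#' @export
read_generative_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(generative_config, raw)
}
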
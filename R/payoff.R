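#' Emotional payoff model
#'
#' Packages the two fitted (or generative) response surfaces together with
#' the coordinate system the feedback simulation runs in. The simulation
#' state is the standardized triple (theta change, gamma change, affective
#' shift): each coordinate is `(x - center) / scale`, so one learning-rate
#' scale works even though the raw predictors span 1e-12 to 1e1. The state
#' is confined to a box (default +/-3 standardized units per coordinate):
#' the fitted quadratic terms are positive, so the unconstrained surface is
#' unbounded above and ascent only has a well-defined end point under a
#' constraint.
#'
#' Payoff modes: `"net"` is predicted positive-affect change minus
#' predicted negative-affect change; `"positive"` is the positive-affect
#' prediction alone; `"negative_reduction"` is the negated negative-affect
#' prediction.
#'
#' @param coef_positive,coef_negative Length-7 coefficient vectors on the
#'   original predictor scale (order: intercept, theta, gamma, shift,
#'   theta-by-shift, gamma squared, shift squared).
#' @param center,scale Length-3 per-predictor centers and scales (theta,
#'   gamma, shift) defining the standardized coordinates.
#' @param bounds 3-by-2 matrix of per-coordinate `[low, high]` bounds in
#'   standardized units (rows theta, gamma, shift), or a single
#'   half-width `b` meaning `[-b, b]` everywhere.
#' @param payoff_mode One of `"net"`, `"positive"`, `"negative_reduction"`.
#' @return An object of class `payoff_model`.
#' @seealso [reference_payoff_model()], [ascend()], [payoff_surface()]
#' @export
payoff_model <- function(coef_positive, coef_negative, center, scale,
                         bounds = 3,
                         payoff_mode = c("net", "positive", "negative_reduction")) {
  payoff_mode <- match.arg(payoff_mode)
  stopifnot(length(coef_positive) == 7L, length(coef_negative) == 7L,
            length(center) == 3L, length(scale) == 3L, all(scale > 0))
  if (length(bounds) == 1L) bounds <- cbind(rep(-bounds, 3L), rep(bounds, 3L))
  bounds <- matrix(as.numeric(bounds), 3L, 2L,
                   dimnames = list(c("theta", "gamma", "shift"), c("low", "high")))
  if (any(bounds[, 1L] >= bounds[, 2L]))
    stop("each coordinate must satisfy bounds low < high", call. = FALSE)
  structure(list(coef_positive = as.numeric(coef_positive),
                 coef_negative = as.numeric(coef_negative),
                 center = as.numeric(center), scale = as.numeric(scale),
                 bounds = bounds, payoff_mode = payoff_mode),
            class = "payoff_model")
}

#' Reference payoff model
#'
#' The payoff model at the package's reference condition: generative
#' coefficients and predictor moments from [default_generative_config()],
#' net payoff, and the +/-3 standardized-unit box.
#'
#' @param config A [generative_config()]; defaults to the reference one.
#' @param ... Passed on to [payoff_model()] (e.g. `payoff_mode`, `bounds`).
#' @return A `payoff_model`.
#' @export
reference_payoff_model <- function(config = default_generative_config(), ...) {
  payoff_model(config$coef_positive, config$coef_negative,
               center = c(config$theta_mean, config$gamma_mean, config$shift_mean),
               scale = c(config$theta_sd, config$gamma_sd, config$shift_sd),
               ...)
}

# Map a standardized state to original predictor coordinates.
to_original <- function(point, model) model$center + model$scale * point

check_in_bounds <- function(point, model, what = "point") {
  point <- as.numeric(point)
  if (length(point) != 3L || anyNA(point))
    stop("'", what, "' must be a numeric length-3 standardized state", call. = FALSE)
  tol <- 1e-9
  if (any(point < model$bounds[, 1L] - tol | point > model$bounds[, 2L] + tol))
    stop("'", what, "' lies outside the simulation bounds", call. = FALSE)
  point
}

# Effective coefficient vector for the configured payoff mode.
mode_coefficients <- function(model) {
  switch(model$payoff_mode,
         net = model$coef_positive - model$coef_negative,
         positive = model$coef_positive,
         negative_reduction = -model$coef_negative)
}

#' Evaluate the emotional payoff at a standardized state
#'
#' @param point Length-3 standardized state (theta, gamma, shift), inside
#'   the model's bounds.
#' @param model A [payoff_model()].
#' @return A single payoff value (PANAS points).
#' @export
payoff <- function(point, model) {
  stopifnot(inherits(model, "payoff_model"))
  point <- check_in_bounds(point, model)
  x <- to_original(point, model)
  drop(surface_terms(x[1L], x[2L], x[3L]) %*% mode_coefficients(model))
}

#' Closed-form payoff gradient
#'
#' Partial derivatives of the quadratic response surface with respect to
#' the three predictors, evaluated at a standardized state and expressed
#' in standardized coordinates (chain rule: each original-scale partial is
#' multiplied by its predictor's scale).
#'
#' On the original scale, with coefficients `b0..b6`:
#' d/dtheta = b1 + b4 * shift; d/dgamma = b2 + 2 b5 * gamma;
#' d/dshift = b3 + b4 * theta + 2 b6 * shift.
#'
#' @inheritParams payoff
#' @return Length-3 named gradient in standardized units.
#' @export
payoff_gradient <- function(point, model) {
  stopifnot(inherits(model, "payoff_model"))
  point <- check_in_bounds(point, model)
  x <- to_original(point, model)
  b <- mode_coefficients(model)
  grad_original <- c(theta = b[2L] + b[5L] * x[3L],
                     gamma = b[3L] + 2 * b[6L] * x[2L],
                     shift = b[4L] + b[5L] * x[1L] + 2 * b[7L] * x[3L])
  grad_original * model$scale
}

#' Projected gradient ascent to a constrained equilibrium
#'
#' Iterates `x[t+1] = clip(x[t] + eta * gradient(x[t]))` in standardized
#' coordinates, stopping when the absolute payoff change falls below
#' `epsilon` (converged) or after `max_iter` updates. The end point is a
#' fixed point of the box-projected ascent map — a constrained stationary
#' point. Under the reference coefficients the shift-squared term is
#' positive, so the trajectory terminates on the box boundary rather than
#' at an interior optimum; for concave surfaces the same iteration
#' converges to the interior vertex.
#'
#' @param model A [payoff_model()].
#' @param eta Length-3 (or scalar) positive learning rates, standardized
#'   units.
#' @param epsilon Convergence tolerance on the payoff change (> 0).
#' @param max_iter Maximum number of updates (>= 1).
#' @param start Length-3 standardized starting state inside the bounds.
#' @return Object of class `emodyn_trajectory`: `states` (`data.frame`
#'   with iteration, standardized and original-scale coordinates, payoff),
#'   `converged`, `iterations`, `stop_reason` (`"tolerance"`,
#'   `"boundary_fixed"`, or `"max_iter"`).
#' @examples
#' traj <- ascend(reference_payoff_model())
#' traj$converged; traj$iterations
#' @export
ascend <- function(model, eta = 0.1, epsilon = 1e-6, max_iter = 50L,
                   start = c(0, 0, 0)) {
  stopifnot(inherits(model, "payoff_model"))
  eta <- rep_len(as.numeric(eta), 3L)
  if (any(eta <= 0)) stop("learning rates 'eta' must all be positive", call. = FALSE)
  if (!(epsilon > 0)) stop("'epsilon' must be positive", call. = FALSE)
  if (max_iter < 1L) stop("'max_iter' must be at least 1", call. = FALSE)
  z <- check_in_bounds(start, model, "start")
  lo <- model$bounds[, 1L]; hi <- model$bounds[, 2L]
  states <- vector("list", max_iter + 1L)
  p <- payoff(z, model)
  states[[1L]] <- c(0, z, to_original(z, model), p)
  converged <- FALSE
  stop_reason <- "max_iter"
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    z_new <- pmin(hi, pmax(lo, z + eta * payoff_gradient(z, model)))
    p_new <- payoff(z_new, model)
    states[[iter + 1L]] <- c(iter, z_new, to_original(z_new, model), p_new)
    moved <- any(z_new != z)
    pinned <- any(z_new == lo | z_new == hi)
    delta_p <- abs(p_new - p)
    z <- z_new; p <- p_new
    if (delta_p < epsilon) {
      converged <- TRUE
      stop_reason <- if (!moved && pinned) "boundary_fixed" else "tolerance"
      break
    }
  }
  states <- do.call(rbind, states[seq_len(iter + 1L)])
  colnames(states) <- c("iteration", "theta_std", "gamma_std", "shift_std",
                        "theta", "gamma", "shift", "payoff")
  structure(list(states = as.data.frame(states), converged = converged,
                 iterations = iter, stop_reason = stop_reason,
                 eta = eta, epsilon = epsilon, max_iter = as.integer(max_iter)),
            class = "emodyn_trajectory")
}

#' @export
print.emodyn_trajectory <- function(x, ...) {
  cat(sprintf("Payoff ascent: %d iterations, %s (%s), final payoff %.6g\n",
              x$iterations, if (x$converged) "converged" else "not converged",
              x$stop_reason, x$states$payoff[nrow(x$states)]))
  invisible(x)
}

#' Payoff surface over a theta/gamma grid at fixed affective shift
#'
#' Evaluates the payoff at every node of a standardized theta-by-gamma
#' grid with the affective shift pinned at a raw PANAS-point value
#' (moderate shift 10 and high shift 20 being the two preset views).
#'
#' @param model A [payoff_model()].
#' @param fixed_shift Affective shift in PANAS points (original scale);
#'   its standardized image must lie inside the bounds.
#' @param theta_grid,gamma_grid Standardized grid coordinates inside the
#'   bounds.
#' @return `data.frame` with columns `theta_std`, `gamma_std`, `theta`,
#'   `gamma`, `payoff` (one row per node), plus attributes `fixed_shift`
#'   and `payoff_mode`.
#' @export
payoff_surface <- function(model, fixed_shift = 10,
                           theta_grid = seq(-3, 3, length.out = 25L),
                           gamma_grid = seq(-3, 3, length.out = 25L)) {
  stopifnot(inherits(model, "payoff_model"))
  shift_std <- (fixed_shift - model$center[3L]) / model$scale[3L]
  grid <- expand.grid(theta_std = theta_grid, gamma_std = gamma_grid)
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    payoff(c(grid$theta_std[i], grid$gamma_std[i], shift_std), model)
  }, numeric(1))
  out <- data.frame(theta_std = grid$theta_std, gamma_std = grid$gamma_std,
                    theta = model$center[1L] + model$scale[1L] * grid$theta_std,
                    gamma = model$center[2L] + model$scale[2L] * grid$gamma_std,
                    payoff = vals)
  attr(out, "fixed_shift") <- fixed_shift
  attr(out, "payoff_mode") <- model$payoff_mode
  out
}
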
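# Fixed sub-stream offsets: each random variable draws from its own seeded
# stream so enlarging the cohort never perturbs earlier participants'
# values for any other variable.
.stream_offsets <- c(theta = 11L, gamma = 23L, shift = 37L,
                     noise_positive = 53L, noise_negative = 71L,
                     pa_pre = 89L, na_pre = 97L,
                     pa_post_draw = 113L, na_post_draw = 127L)

# Draw n N(mean, sd) values from the sub-stream `which`, leaving the
# caller's RNG state untouched.
stream_rnorm <- function(n, mean, sd, seed, which) {
  off <- .stream_offsets[[which]]
  local_seed((as.integer(seed) + off) %% .Machine$integer.max,
             stats::rnorm(n, mean, sd))
}

# Evaluate `expr` under a temporary seed, restoring the global RNG state.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Polynomial feature row(s) for the shared response surface, in the fixed
# coefficient order. Vectorized over participants.
surface_terms <- function(theta, gamma, shift) {
  cbind(intercept = rep(1, length(theta)),
        theta_change = theta,
        gamma_change = gamma,
        affective_shift = shift,
        theta_x_shift = theta * shift,
        gamma_sq = gamma^2,
        shift_sq = shift^2)
}

#' Generate a synthetic participant cohort
#'
#' Draws EEG change scores and affective shifts from the configured Gaussian
#' distributions and produces both affect-change outcomes from the quadratic
#' response-surface equations plus independent Gaussian noise. The result
#' has the statistical structure the downstream regression assumes, so the
#' whole pipeline is testable without any recorded data.
#'
#' In `shift_mode = "latent"` the affective shift is drawn directly and
#' PANAS scores are back-filled around it. In `shift_mode = "derived"` PANAS
#' pre/post subscale scores are drawn first and the affective shift is
#' computed from them with [affect_deltas()], reproducing the measurement
#' circularity of shift scores constructed from the same instrument as the
#' outcomes; stored post scores are then realigned to `pre + delta` so each
#' record's outcome columns stay consistent with its score columns.
#'
#' With `emit_items = TRUE` every administration also carries 20 Likert
#' items (columns `pa01..pa10`/`na01..na10` with `_pre`/`_post` suffixes)
#' whose subscale sums equal the stored scores; scores are then rounded and
#' clipped to the legal 10--50 range and the number of clipped values is
#' recorded in `attr(cohort, "n_clipped")`.
#'
#' @param config A [generative_config()].
#' @return A `data.frame` with one row per participant: `participant_id`,
#'   PANAS subscale scores (`pa_pre`, `na_pre`, `pa_post`, `na_post`),
#'   `theta_change`, `gamma_change`, `affective_shift`, `delta_positive`,
#'   `delta_negative`, optional item columns. Attributes: `shift_mode`,
#'   `n_clipped`, `config`.
#' @examples
#' cohort <- generate_cohort(default_generative_config(n_participants = 10))
#' head(cohort[, c("theta_change", "affective_shift", "delta_negative")])
#' @export
generate_cohort <- function(config) {
  validate_generative_config(config)
  n <- config$n_participants
  seed <- config$seed

  theta <- stream_rnorm(n, config$theta_mean, config$theta_sd, seed, "theta")
  gamma <- stream_rnorm(n, config$gamma_mean, config$gamma_sd, seed, "gamma")

  # Pre-session subscale scores: positive affect centred moderately high,
  # negative moderately low, as in non-clinical student samples.
  pa_pre <- pmin(50, pmax(10, stream_rnorm(n, 28, 6, seed, "pa_pre")))
  na_pre <- pmin(50, pmax(10, stream_rnorm(n, 22, 6, seed, "na_pre")))

  if (config$shift_mode == "latent") {
    shift <- stream_rnorm(n, config$shift_mean, config$shift_sd, seed, "shift")
  } else {
    # Draw provisional post scores so the shift is computed from genuine
    # score arithmetic; each subscale change carries half the configured
    # mean and sd/sqrt(2) so their difference has the configured moments.
    pa_post_draw <- pa_pre +
      stream_rnorm(n, config$shift_mean / 2, config$shift_sd / sqrt(2), seed, "pa_post_draw")
    na_post_draw <- na_pre +
      stream_rnorm(n, -config$shift_mean / 2, config$shift_sd / sqrt(2), seed, "na_post_draw")
    shift <- vapply(seq_len(n), function(i) {
      affect_deltas(panas_scores(pa_pre[i], na_pre[i]),
                    panas_scores(pa_post_draw[i], na_post_draw[i]),
                    shift_mode = "net")$affective_shift
    }, numeric(1))
  }

  terms <- surface_terms(theta, gamma, shift)
  eps_pos <- stream_rnorm(n, 0, config$noise_sd_positive, seed, "noise_positive")
  eps_neg <- stream_rnorm(n, 0, config$noise_sd_negative, seed, "noise_negative")
  delta_positive <- drop(terms %*% config$coef_positive) + eps_pos
  delta_negative <- drop(terms %*% config$coef_negative) + eps_neg

  pa_post <- pa_pre + delta_positive
  na_post <- na_pre + delta_negative

  cohort <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    pa_pre = pa_pre, na_pre = na_pre,
    pa_post = pa_post, na_post = na_post,
    theta_change = theta, gamma_change = gamma,
    affective_shift = shift,
    delta_positive = delta_positive,
    delta_negative = delta_negative,
    stringsAsFactors = FALSE
  )

  n_clipped <- 0L
  if (config$emit_items) {
    score_cols <- c("pa_pre", "na_pre", "pa_post", "na_post")
    for (col in score_cols) {
      rounded <- round(cohort[[col]])
      clipped <- pmin(50, pmax(10, rounded))
      n_clipped <- n_clipped + sum(clipped != cohort[[col]])
      cohort[[col]] <- clipped
    }
    # Deltas restated from the clipped scores so record-level identities hold.
    cohort$delta_positive <- cohort$pa_post - cohort$pa_pre
    cohort$delta_negative <- cohort$na_post - cohort$na_pre
    items <- list(
      pa_pre = t(vapply(cohort$pa_pre, backfill_items, numeric(10))),
      na_pre = t(vapply(cohort$na_pre, backfill_items, numeric(10))),
      pa_post = t(vapply(cohort$pa_post, backfill_items, numeric(10))),
      na_post = t(vapply(cohort$na_post, backfill_items, numeric(10)))
    )
    for (key in names(items)) {
      sub <- sub("_(pre|post)$", "", key)
      when <- sub("^(pa|na)_", "", key)
      colnames(items[[key]]) <- sprintf("%s%02d_%s", sub, 1:10, when)
      cohort <- cbind(cohort, as.data.frame(items[[key]]))
    }
  }

  attr(cohort, "shift_mode") <- config$shift_mode
  attr(cohort, "n_clipped") <- n_clipped
  attr(cohort, "config") <- config
  cohort
}

# Distribute an integer subscale score (10..50) over ten Likert items by
# round-robin increments from all-ones; deterministic.
backfill_items <- function(score) {
  score <- as.integer(round(score))
  stopifnot(score >= 10L, score <= 50L)
  extra <- score - 10L
  items <- rep(1L + extra %/% 10L, 10L)
  rem <- extra %% 10L
  if (rem > 0L) items[seq_len(rem)] <- items[seq_len(rem)] + 1L
  items
}
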
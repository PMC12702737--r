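# Canonical 20-item PANAS ordering: positions of the positive-affect items;
# the remaining ten are negative-affect items.
PANAS_POSITIVE_ITEMS <- c(1L, 3L, 5L, 9L, 10L, 12L, 14L, 16L, 17L, 19L)

#' PANAS subscale scores
#'
#' Lightweight container for one administration's positive-affect (`pa`)
#' and negative-affect (`na`) subscale scores.
#'
#' @param pa,na Subscale scores (sum of ten 1--5 items, so 10--50 when
#'   item-derived).
#' @return An object of class `panas_scores`.
#' @export
panas_scores <- function(pa, na) {
  stopifnot(is.numeric(pa), is.numeric(na), length(pa) == 1L, length(na) == 1L)
  structure(list(pa = as.numeric(pa), na = as.numeric(na)),
            class = "panas_scores")
}

#' Score a 20-item PANAS administration
#'
#' Sums the ten positive-affect and ten negative-affect items of the
#' Positive and Negative Affect Schedule. Item-to-subscale assignment
#' follows the canonical 20-item ordering and can be overridden.
#'
#' @param items Exactly 20 integer responses, each in 1--5.
#' @param positive_items Positions (within `items`) of the ten
#'   positive-affect items.
#' @return A [panas_scores()] object; each subscale lies in 10--50.
#' @examples
#' score_panas(rep(3, 20))   # pa = 30, na = 30
#' @export
score_panas <- function(items, positive_items = PANAS_POSITIVE_ITEMS) {
  if (length(items) != 20L)
    stop("PANAS requires exactly 20 items, got ", length(items), call. = FALSE)
  bad <- which(is.na(items) | items < 1 | items > 5 | items != round(items))
  if (length(bad) > 0L)
    stop("invalid PANAS item response at index ", paste(bad, collapse = ", "),
         " (each item must be an integer in 1..5)", call. = FALSE)
  if (length(positive_items) != 10L || anyDuplicated(positive_items) ||
      any(positive_items < 1L | positive_items > 20L))
    stop("'positive_items' must be 10 distinct positions in 1..20", call. = FALSE)
  pa <- sum(items[positive_items])
  na <- sum(items[-positive_items])
  panas_scores(pa, na)
}

#' Affect-change variables from pre/post PANAS scores
#'
#' Computes the two outcome variables, `delta_positive = post.pa - pre.pa`
#' and `delta_negative = post.na - pre.na`, together with the affective
#' shift summarizing overall subjective reappraisal. The default `"net"`
#' mode defines the shift as `delta_positive - delta_negative`
#' (improvement-signed: gains in positive affect and losses in negative
#' affect both raise it); `"sum"` adds the two deltas instead. The mode is
#' recorded in the result so downstream consumers never mix definitions.
#'
#' @param pre,post [panas_scores()] for the pre- and post-session
#'   administrations.
#' @param shift_mode `"net"` (default) or `"sum"`.
#' @return A list of class `affect_deltas`: `delta_positive`,
#'   `delta_negative`, `affective_shift`, `shift_mode`.
#' @examples
#' affect_deltas(panas_scores(20, 30), panas_scores(30, 20))
#' @export
affect_deltas <- function(pre, post, shift_mode = c("net", "sum")) {
  stopifnot(inherits(pre, "panas_scores"), inherits(post, "panas_scores"))
  shift_mode <- match.arg(shift_mode)
  dp <- post$pa - pre$pa
  dn <- post$na - pre$na
  shift <- switch(shift_mode, net = dp - dn, sum = dp + dn)
  structure(list(delta_positive = dp, delta_negative = dn,
                 affective_shift = shift, shift_mode = shift_mode),
            class = "affect_deltas")
}

#' Append affect-change columns to a cohort table
#'
#' Recomputes `delta_positive`, `delta_negative` and `affective_shift` from
#' a cohort's score columns (or item columns when present), overwriting any
#' existing derived columns.
#'
#' @param cohort A cohort `data.frame` with `pa_pre`, `na_pre`, `pa_post`,
#'   `na_post` columns (or the full item columns).
#' @param shift_mode Passed to [affect_deltas()].
#' @return The cohort with refreshed derived columns; the shift mode is
#'   stored in `attr(cohort, "shift_mode")`.
#' @export
derive_affect_columns <- function(cohort, shift_mode = c("net", "sum")) {
  shift_mode <- match.arg(shift_mode)
  needed <- c("pa_pre", "na_pre", "pa_post", "na_post")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols) > 0L)
    stop("cohort is missing PANAS score columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  res <- lapply(seq_len(nrow(cohort)), function(i) {
    affect_deltas(panas_scores(cohort$pa_pre[i], cohort$na_pre[i]),
                  panas_scores(cohort$pa_post[i], cohort$na_post[i]),
                  shift_mode = shift_mode)
  })
  cohort$delta_positive <- vapply(res, `[[`, numeric(1), "delta_positive")
  cohort$delta_negative <- vapply(res, `[[`, numeric(1), "delta_negative")
  cohort$affective_shift <- vapply(res, `[[`, numeric(1), "affective_shift")
  attr(cohort, "shift_mode") <- shift_mode
  cohort
}
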
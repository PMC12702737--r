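# Format every numeric column with 17 significant digits so CSV round
# trips are lossless for doubles (including 1e-11-scale band powers).
format_numeric_frame <- function(df) {
  for (col in names(df)) {
    if (is.numeric(df[[col]]))
      df[[col]] <- sprintf("%.17g", df[[col]])
  }
  df
}

COHORT_REQUIRED_COLS <- c("participant_id", "pa_pre", "na_pre", "pa_post",
                          "na_post", "theta_change", "gamma_change",
                          "affective_shift", "delta_positive", "delta_negative")

#' Write or read a cohort table
#'
#' Fixed CSV dialect: UTF-8, header row, `.` decimal separator, no index
#' column, one participant per row. Numeric fields are written with 17
#' significant digits, so the write/read round trip is lossless at full
#' double precision (scientific-notation magnitudes like 1e-11 included).
#'
#' @param cohort Cohort `data.frame` (see [generate_cohort()]).
#' @param path CSV file path.
#' @return `read_cohort()` returns the cohort `data.frame`;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(COHORT_REQUIRED_COLS, names(cohort))
  if (length(missing_cols) > 0L)
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.csv(format_numeric_frame(cohort), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  missing_cols <- setdiff(COHORT_REQUIRED_COLS, names(cohort))
  if (length(missing_cols) > 0L)
    stop("cohort file '", path, "' is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  numeric_cols <- setdiff(COHORT_REQUIRED_COLS, "participant_id")
  for (col in numeric_cols) {
    bad <- which(is.na(cohort[[col]]))
    if (length(bad) > 0L)
      stop(sprintf("cohort file '%s': column '%s' has a missing/unparseable value at row %d",
                   path, col, bad[1L]), call. = FALSE)
  }
  cohort
}

# FNV-1a hash of a configuration's canonical JSON form; gives every report
# a stable fingerprint of the settings that produced it.
config_hash <- function(config) {
  strip_classes <- function(x)
    if (is.list(x)) lapply(unclass(x), strip_classes) else x
  txt <- jsonlite::toJSON(strip_classes(config), auto_unbox = TRUE,
                          digits = NA, null = "null")
  bytes <- utf8ToInt(as.character(txt))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Per-stage sub-seeds derived from the global seed by fixed offsets, so
# inserting a stage never reshuffles another stage's stream.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, stats = 211L, regress = 307L,
               compare = 401L, payoff = 503L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Pipeline configuration
#'
#' Bundles every stage's settings with one global seed. Per-stage
#' sub-seeds are derived from the global seed by fixed offsets.
#'
#' @param generative A [generative_config()] for the simulate stage.
#' @param stages Character subset of
#'   `c("simulate", "stats", "regress", "compare", "payoff")`, run in
#'   dependency order.
#' @param shift_mode Affective-shift definition for score-derived columns.
#' @param n_resamples,level Bootstrap settings for the stats and regress
#'   stages.
#' @param folds,repeats Cross-validation settings for the compare stage.
#' @param eta,epsilon,max_iter Ascent settings for the payoff stage.
#' @param seed Global integer seed.
#' @param out_dir Optional directory; when set, the cohort CSV
#'   (`cohort.csv`), configuration (`config.yaml`) and report
#'   (`report.json`) are written there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generative = default_generative_config(),
                            stages = c("simulate", "stats", "regress",
                                       "compare", "payoff"),
                            shift_mode = c("net", "sum"),
                            n_resamples = 1000L, level = 0.95,
                            folds = 5L, repeats = 20L,
                            eta = 0.1, epsilon = 1e-6, max_iter = 50L,
                            seed = 42L, out_dir = NULL) {
  shift_mode <- match.arg(shift_mode)
  stages <- match.arg(stages, several.ok = TRUE)
  validate_generative_config(generative)
  structure(list(generative = generative, stages = stages,
                 shift_mode = shift_mode,
                 n_resamples = as.integer(n_resamples), level = level,
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 eta = eta, epsilon = epsilon, max_iter = as.integer(max_iter),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the enabled stages in dependency order: cohort simulation, the
#' nonparametric battery, regression with bootstrapped coefficients for
#' both outcomes (plus the exploratory mediation checks), the
#' multimodal/unimodal model comparison, and the payoff ascent. Any stage
#' failure aborts with an error naming the stage. The report is fully
#' re-derivable from the configuration: every stochastic stage records its
#' derived sub-seed and the report carries a hash of the configuration.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `emodyn_report` with one element per executed
#'   stage plus `config_hash`, `seed` and per-stage `elapsed` seconds.
#' @examples
#' cfg <- pipeline_config(default_generative_config(n_participants = 30),
#'                        n_resamples = 50, repeats = 2, seed = 7)
#' report <- run_pipeline(cfg)
#' names(report$stages)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(config_hash = config_hash(config), seed = config$seed,
                 stages = list(), elapsed = list())
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    result <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    report$stages[[name]] <<- result
    report$elapsed[[name]] <<- proc.time()[["elapsed"]] - t0
    result
  }

  cohort <- NULL
  if ("simulate" %in% config$stages) {
    cohort <- run_stage("simulate", function() {
      gen <- config$generative
      gen$seed <- stage_seed(config$seed, "simulate")
      generate_cohort(gen)
    })
  } else {
    stop("pipeline requires the 'simulate' stage (no external cohort source configured)",
         call. = FALSE)
  }

  if ("stats" %in% config$stages)
    run_stage("stats", function()
      nonparametric_battery(cohort, n_resamples = config$n_resamples,
                            level = config$level,
                            seed = stage_seed(config$seed, "stats")))

  fits <- NULL
  if ("regress" %in% config$stages) {
    fits <- run_stage("regress", function() {
      seed_r <- stage_seed(config$seed, "regress")
      list(
        delta_positive = list(
          fit = fit_cohort_outcome(cohort, "delta_positive"),
          bootstrap = bootstrap_coefficients(cohort, "delta_positive",
                                             config$n_resamples, config$level,
                                             seed_r)),
        delta_negative = list(
          fit = fit_cohort_outcome(cohort, "delta_negative"),
          bootstrap = bootstrap_coefficients(cohort, "delta_negative",
                                             config$n_resamples, config$level,
                                             seed_r + 1L)),
        mediation = list(
          theta = mediation_indirect(cohort, "theta_change",
                                     outcome = "delta_negative",
                                     n_boot = config$n_resamples,
                                     level = config$level, seed = seed_r + 2L),
          gamma = mediation_indirect(cohort, "gamma_change",
                                     outcome = "delta_positive",
                                     n_boot = config$n_resamples,
                                     level = config$level, seed = seed_r + 3L)))
    })
  }

  if ("compare" %in% config$stages)
    run_stage("compare", function()
      compare_models(cohort, outcome = "delta_positive",
                     folds = config$folds, repeats = config$repeats,
                     seed = stage_seed(config$seed, "compare")))

  if ("payoff" %in% config$stages)
    run_stage("payoff", function() {
      model <- if (!is.null(fits))
        payoff_model(fits$delta_positive$fit$coefficients,
                     fits$delta_negative$fit$coefficients,
                     center = c(mean(cohort$theta_change),
                                mean(cohort$gamma_change),
                                mean(cohort$affective_shift)),
                     scale = c(stats::sd(cohort$theta_change),
                               stats::sd(cohort$gamma_change),
                               stats::sd(cohort$affective_shift)))
      else reference_payoff_model(config$generative)
      ascend(model, eta = config$eta, epsilon = config$epsilon,
             max_iter = config$max_iter)
    })

  class(report) <- "emodyn_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
    write_generative_config(config$generative,
                            file.path(config$out_dir, "config.yaml"))
    jsonlite::write_json(report_summary(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# Flatten a report into JSON-friendly scalars/tables.
report_summary <- function(report) {
  out <- list(config_hash = report$config_hash, seed = report$seed,
              elapsed = report$elapsed)
  st <- report$stages
  if (!is.null(st$simulate))
    out$simulate <- list(n_participants = nrow(st$simulate),
                         n_clipped = attr(st$simulate, "n_clipped"))
  if (!is.null(st$stats))
    out$stats <- list(
      n_tests = st$stats$n_tests,
      normality = lapply(st$stats$normality, function(t)
        list(statistic = t$statistic, p_value = t$p_value, normal = t$normal)),
      bootstrap_means = lapply(st$stats$bootstrap_means, function(b)
        list(estimate = b$estimate, ci_low = b$ci_low, ci_high = b$ci_high)))
  if (!is.null(st$regress))
    out$regress <- lapply(st$regress[c("delta_positive", "delta_negative")],
                          function(m) list(
                            r_squared = m$fit$r_squared,
                            residual_sd = m$fit$residual_sd,
                            coefficients = as.list(m$fit$coefficients),
                            ci_low = stats::setNames(m$bootstrap$ci_low, m$bootstrap$term),
                            ci_high = stats::setNames(m$bootstrap$ci_high, m$bootstrap$term)))
  if (!is.null(st$compare))
    out$compare <- st$compare$table
  if (!is.null(st$payoff))
    out$payoff <- list(converged = st$payoff$converged,
                       iterations = st$payoff$iterations,
                       stop_reason = st$payoff$stop_reason,
                       final_payoff = st$payoff$states$payoff[nrow(st$payoff$states)])
  out
}

#' @export
print.emodyn_report <- function(x, ...) {
  cat("Pipeline report (config ", x$config_hash, ", seed ", x$seed, ")\n",
      sep = "")
  for (nm in names(x$stages))
    cat(sprintf("  %-9s %6.2f s\n", nm, x$elapsed[[nm]]))
  invisible(x)
}
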
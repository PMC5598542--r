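#' Read and write trial tables
#'
#' Trial tables are plain comma-separated text with header columns
#' `subject_id, group, condition, block_index, trial_index, stimulus,
#' action, feedback_shown, reinforcement, correct` (trial indices 0-based
#' within subject-condition).  `read_trials()` validates the schema and
#' reports the first offending row of any violation.
#'
#' @param path File path.
#' @return `read_trials()`: the validated trial table (a data frame).
#' @export
read_trials <- function(path) {
  if (!file.exists(path))
    stop_avoidrl(paste("no such file:", path), "avoidrl_parse_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(df)
}

#' @rdname read_trials
#' @param trials Trial table to write.
#' @return `write_trials()`: `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a trial table against the schema
#'
#' @param trials Data frame to check.
#' @return The table, with integer/logical columns coerced.
#' @export
validate_trials <- function(trials) {
  need <- c("subject_id", "group", "condition", "block_index", "trial_index",
            "stimulus", "action", "feedback_shown", "reinforcement",
            "correct")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop_avoidrl(paste("missing column(s):", paste(miss, collapse = ", ")),
                 "avoidrl_parse_error")
  if (nrow(trials) == 0L) return(trials)
  bad_row <- function(ok, what) {
    if (!all(ok))
      stop_avoidrl(sprintf("%s at row %d", what, which(!ok)[1]),
                   "avoidrl_parse_error")
  }
  bad_row(trials$group %in% c("control", "anx"), "unknown group label")
  bad_row(trials$condition %in% c("safe", "threat"),
          "unknown condition label")
  bad_row(trials$stimulus %in% STIMULI, "unknown stimulus label")
  bad_row(trials$action %in% c("go", "nogo"), "unknown action label")
  r <- trials$reinforcement
  bad_row(is.finite(r) & r == as.integer(r) & r %in% c(-1, 0, 1),
          "reinforcement outside {-1, 0, +1}")
  win <- trials$stimulus %in% c("GW", "NGW")
  bad_row(!(win & r == -1), "negative reinforcement on a win stimulus")
  bad_row(!(!win & r == 1), "positive reinforcement on an avoid stimulus")
  trials$reinforcement <- as.integer(r)
  trials$block_index <- as.integer(trials$block_index)
  trials$trial_index <- as.integer(trials$trial_index)
  trials$feedback_shown <- as.logical(trials$feedback_shown)
  trials$correct <- as.logical(trials$correct)
  trials
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) a cohort, fit the requested model/scheme grid,
#' select the winner by iBIC, run the posterior predictive simulation with
#' the winning fit, and test group/condition effects on the requested
#' parameter of the winning model.  All randomness flows from the seeds in
#' the configuration; re-running the same configuration reproduces the
#' outputs.
#'
#' @param config Nested list (or path to a YAML file) with optional
#'   entries: `seed`; `design` (arguments to [task_design()]); `cohort`
#'   (arguments to [cohort_spec()]) or `trials` (path to a trial CSV);
#'   `models` (character vector of variant names, or "all"); `schemes`
#'   (scheme names, or "all"); `fit` (arguments to [em_config()]);
#'   `n_replicates` (posterior predictive sessions per unit);
#'   `stats` (list with `parameter`, `n_permutations`); `out_dir`
#'   (directory for CSV/YAML outputs; omit to keep results in memory).
#' @return List with `manifest`, `trials`, `comparison`, `winner_fit`,
#'   `predicted`, `curves_observed`, `curves_predicted`, `accuracy`,
#'   `stats`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  design <- do.call(task_design, config$design %||% list())

  # validate model/scheme names before any compute
  model_names <- config$models %||% "all"
  if (identical(model_names, "all")) model_names <- names(list_model_specs())
  models <- lapply(model_names, gng_model)
  scheme_names <- config$schemes %||% "all"
  if (identical(scheme_names, "all")) scheme_names <- names(partition_schemes())
  schemes <- lapply(scheme_names, get_scheme)

  fit_args <- config$fit %||% list()
  if (is.null(fit_args$seed)) fit_args$seed <- derive_seed(seed, "fit")
  fit_config <- do.call(em_config, fit_args)

  if (!is.null(config$trials)) {
    trials <- read_trials(config$trials)
  } else {
    cohort_args <- config$cohort %||% list()
    if (is.null(cohort_args$seed)) cohort_args$seed <- derive_seed(seed, "sim")
    cspec <- do.call(cohort_spec, cohort_args)
    trials <- generate_cohort(cspec, design)
  }

  comparison <- compare_models(trials, models, schemes, fit_config)
  winner_fit <- comparison$fits[[comparison$winner$key]]

  n_rep <- config$n_replicates %||% 10L
  predicted <- simulate_from_fit(winner_fit, design, n_replicates = n_rep,
                                 seed = derive_seed(seed, "predict"))
  stats_args <- config$stats %||% list()
  parameter <- stats_args$parameter %||%
    intersect(c("avoidance_bias", "approach_avoid_bias"),
              winner_fit$model$params)[1]
  stats <- if (!is.na(parameter) && !is.null(parameter) &&
               parameter %in% winner_fit$model$params &&
               length(unique(trials$group)) == 2L &&
               length(unique(trials$condition)) == 2L) {
    parameter_group_tests(winner_fit, parameter,
                          n_permutations = stats_args$n_permutations %||%
                            10000L,
                          seed = derive_seed(seed, "stats"))
  } else NULL

  result <- list(
    manifest = NULL, trials = trials, comparison = comparison,
    winner_fit = winner_fit, predicted = predicted,
    curves_observed = pgo_curves(trials),
    curves_predicted = if (nrow(predicted)) pgo_curves(predicted) else NULL,
    accuracy = accuracy_summary(trials), stats = stats)

  manifest <- list(
    package_version = as.character(utils::packageVersion("avoidrl")),
    created = format(Sys.time(), tz = "UTC"),
    seed = seed, config = config,
    winner = comparison$winner[c("model", "scheme")],
    stages = c("simulate", "compare", "predict", "stats"))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(trials = file.path(config$out_dir, "trials.csv"),
               comparison = file.path(config$out_dir, "comparison.csv"),
               predicted = file.path(config$out_dir, "predicted.csv"))
    write_trials(trials, paths["trials"])
    utils::write.csv(comparison$table, paths["comparison"],
                     row.names = FALSE)
    if (nrow(predicted)) utils::write.csv(predicted, paths["predicted"],
                                          row.names = FALSE)
    manifest$digests <- as.list(tools::md5sum(unname(paths[file.exists(paths)])))
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  }
  result$manifest <- manifest
  result
}
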
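#' Posterior predictive simulation from a fitted model
#'
#' Re-plays the task with a computer making choices as each fitted unit:
#' every subject-condition unit is simulated `n_replicates` times at its
#' posterior-mode parameters on a fresh schedule (fresh random feedback,
#' not a replay of the fitted session's outcomes).
#'
#' @param fit A `gng_fit` from [fit_model()] or a `gng_em_fit`.
#' @param design A [task_design()].
#' @param n_replicates Sessions per unit (0 gives an empty table).
#' @param seed Integer seed.
#' @return Trial table in the cohort format with an extra `replicate`
#'   column.
#' @export
simulate_from_fit <- function(fit, design = task_design(), n_replicates = 10L,
                              seed = 1L) {
  if (inherits(fit, "gng_fit")) {
    pt <- fit_parameter_table(fit, space = "unconstrained")
    model <- fit$model
  } else if (inherits(fit, "gng_em_fit")) {
    pt <- parameter_table(fit, space = "unconstrained")
    model <- fit$model
  } else stop_avoidrl("fit must be a gng_fit or gng_em_fit",
                      "avoidrl_spec_error")
  if (n_replicates == 0L) {
    out <- empty_trials()
    out$replicate <- integer(0)
    return(out)
  }
  pcols <- model$params
  bad <- !stats::complete.cases(pt[, pcols, drop = FALSE])
  if (any(bad))
    stop_avoidrl(paste("missing posterior-mode parameters for unit(s):",
                       paste(pt$unit_id[bad], collapse = ", ")),
                 "avoidrl_spec_error")
  with_seed(derive_seed(seed, "predictive"), {
    rows <- list()
    for (i in seq_len(nrow(pt))) {
      nat <- to_natural(model, unlist(pt[i, pcols]))
      for (r in seq_len(n_replicates)) {
        sched <- build_session_schedule(design,
                                        seed = stats::runif(1, 1, 2^30))
        half <- sched[sched$condition == pt$condition[i], , drop = FALSE]
        tr <- simulate_agent(half, model, nat,
                             seed = stats::runif(1, 1, 2^30),
                             contingency = design$feedback_contingency)
        tr$condition <- pt$condition[i]
        rows[[length(rows) + 1L]] <- cbind(
          subject_id = pt$subject_id[i], group = pt$group[i], tr,
          replicate = r, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' P(go) learning curves by trial type
#'
#' Average probability of responding per stimulus-presentation position,
#' split by group, condition and stimulus type: the model-validation
#' summary comparing simulated and observed behaviour over time.  The
#' position index counts presentations of that stimulus within a
#' subject-condition session (and replicate, when present), so curves are
#' aligned on learning opportunity.
#'
#' @param trials Trial table (real, synthetic or posterior predictive).
#' @return Data frame with columns `group`, `condition`, `stimulus`,
#'   `position`, `p_go`, `n_sessions`.
#' @export
pgo_curves <- function(trials) {
  need <- c("subject_id", "group", "condition", "trial_index", "stimulus",
            "action")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop_avoidrl(paste("missing column(s):", paste(miss, collapse = ", ")),
                 "avoidrl_parse_error")
  check_stimulus(trials$stimulus)
  rep_id <- if ("replicate" %in% names(trials)) trials$replicate else 0L
  sess <- interaction(trials$subject_id, trials$condition, rep_id, drop = TRUE)
  ord <- order(sess, trials$trial_index)
  trials <- trials[ord, , drop = FALSE]
  sess <- sess[ord]
  position <- stats::ave(seq_len(nrow(trials)),
                         interaction(sess, trials$stimulus, drop = TRUE),
                         FUN = seq_along)
  go <- as.numeric(trials$action == "go")
  agg <- stats::aggregate(
    go, by = list(group = trials$group, condition = trials$condition,
                  stimulus = trials$stimulus, position = position),
    FUN = function(x) c(mean(x), length(x)))
  out <- data.frame(agg[, c("group", "condition", "stimulus", "position")],
                    p_go = agg$x[, 1], n_sessions = agg$x[, 2])
  out[order(out$group, out$condition, out$stimulus, out$position), ]
}

#' Accuracy by unit and trial type
#'
#' Mean proportion of instrumentally correct choices per subject-condition
#' (and replicate, when present) and stimulus type.
#'
#' @param trials Trial table with a logical `correct` column.
#' @return Data frame with columns `subject_id`, `group`, `condition`
#'   (plus `replicate` if present), `stimulus`, `accuracy`.
#' @export
accuracy_summary <- function(trials) {
  by <- list(subject_id = trials$subject_id, group = trials$group,
             condition = trials$condition, stimulus = trials$stimulus)
  if ("replicate" %in% names(trials)) by$replicate <- trials$replicate
  agg <- stats::aggregate(as.numeric(trials$correct), by = by, FUN = mean)
  names(agg)[ncol(agg)] <- "accuracy"
  agg
}

#' Overall go rate per unit
#'
#' @param trials Trial table.
#' @return Data frame with columns `subject_id`, `group`, `condition` and
#'   `p_go`.
#' @export
go_rate_summary <- function(trials) {
  agg <- stats::aggregate(as.numeric(trials$action == "go"),
                          by = list(subject_id = trials$subject_id,
                                    group = trials$group,
                                    condition = trials$condition),
                          FUN = mean)
  names(agg)[ncol(agg)] <- "p_go"
  agg
}

#' Plot P(go) learning curves
#'
#' One panel per group x condition, one curve per stimulus type, mirroring
#' the standard presentation of behaviour over time on this task.
#'
#' @param curves Output of [pgo_curves()].
#' @return A ggplot object.
#' @export
plot_pgo_curves <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_avoidrl("plot_pgo_curves requires the ggplot2 package",
                 "avoidrl_spec_error")
  ggplot2::ggplot(curves, ggplot2::aes(x = position, y = p_go,
                                       colour = stimulus)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(group ~ condition) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "stimulus presentation", y = "P(go)",
                  colour = "trial type") +
    ggplot2::theme_minimal()
}

empty_trials <- function() {
  data.frame(subject_id = character(0), group = character(0),
             condition = character(0), block_index = integer(0),
             trial_index = integer(0), stimulus = character(0),
             action = character(0), feedback_shown = logical(0),
             reinforcement = integer(0), correct = logical(0),
             stringsAsFactors = FALSE)
}
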
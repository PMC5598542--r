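#' Simulate one agent on a trial schedule
#'
#' Plays the schedule with a model agent: on each trial the action is
#' sampled from the model's lapse-squashed softmax probabilities given the
#' current latent state, probabilistic feedback is drawn, and the latent
#' state is updated with the sampled outcome.  The latent state is carried
#' across the whole schedule, so pass one subject-condition's half of a
#' session when conditions are modelled as separate learning contexts.
#'
#' @param schedule Data frame from [build_session_schedule()] (or a subset
#'   of its rows).
#' @param spec A `gng_model`.
#' @param params Natural-space parameter vector for `spec`.
#' @param seed Integer seed; the simulation is deterministic given the seed.
#' @param contingency Feedback contingency (see [sample_feedback()]).
#' @return Data frame of trial records with columns `condition`,
#'   `block_index`, `trial_index` (0-based within the schedule played),
#'   `stimulus`, `action`, `feedback_shown`, `reinforcement`, `correct`.
#' @export
simulate_agent <- function(schedule, spec, params, seed = 1L,
                           contingency = 0.8) {
  stopifnot(inherits(spec, "gng_model"))
  n <- nrow(schedule)
  if (isTRUE(spec$random)) {
    ex <- list(theta = c(1, 1, 0, 0, 1, 0, 0, 0), has_action_bias = FALSE,
               has_appavo = FALSE)  # lapse 1: pure coin flips
  } else {
    ex <- expand_theta(spec, params)
  }
  th <- ex$theta
  with_seed(derive_seed(seed, "agent"), {
    s_code <- match(schedule$stimulus, STIMULI)
    win <- s_code %in% c(1L, 3L)
    req_go <- s_code %in% c(1L, 2L)
    qgo <- qng <- v <- numeric(4)
    go <- logical(n)
    reinf <- integer(n)
    u_act <- stats::runif(n)
    u_fb <- stats::runif(n)
    for (t in seq_len(n)) {
      s <- s_code[t]
      w_go <- qgo[s]
      if (ex$has_action_bias) w_go <- w_go + th[6]
      if (ex$has_appavo) w_go <- w_go + (if (win[t]) th[7] else th[8]) * v[s]
      p_go <- stats::plogis(w_go - qng[s]) * (1 - th[5]) + th[5] / 2
      a_go <- u_act[t] < p_go
      go[t] <- a_go
      correct <- a_go == req_go[t]
      favourable <- correct == (u_fb[t] < contingency)
      r <- if (win[t]) {
        if (favourable) 1L else 0L
      } else {
        if (favourable) 0L else -1L
      }
      reinf[t] <- r
      sens <- if (win[t]) th[1] else th[2]
      lr <- if (win[t]) th[3] else th[4]
      target <- sens * r
      if (a_go) qgo[s] <- qgo[s] + lr * (target - qgo[s])
      else      qng[s] <- qng[s] + lr * (target - qng[s])
      v[s] <- v[s] + lr * (target - v[s])
    }
    data.frame(
      condition = schedule$condition,
      block_index = schedule$block_index,
      trial_index = seq_len(n) - 1L,
      stimulus = schedule$stimulus,
      action = ifelse(go, "go", "nogo"),
      feedback_shown = reinf != 0L,
      reinforcement = reinf,
      correct = go == req_go,
      stringsAsFactors = FALSE)
  })
}

#' Specification of a synthetic cohort
#'
#' Describes the generative populations for a two-group (control vs mood
#' and anxiety) cohort.  Per subject and condition, unconstrained-space
#' parameters are drawn from a group-and-condition-specific Gaussian
#' population and pushed through the model transforms.  The two groups
#' share all population means except the avoidance bias:
#' `effect_avoidance_group` shifts the anxiety group's unconstrained
#' (log-scale) avoidance-bias mean in both conditions, and
#' `effect_avoidance_threat_potentiation` adds a further shift under
#' threat, emulating heightened, threat-potentiated avoidance in the
#' clinical group.  With both effects zero the four populations are
#' identical.
#'
#' @param n_per_group Subjects per group (>= 1).
#' @param model A `gng_model`; defaults to the eight-parameter winning
#'   variant.
#' @param population_means Named unconstrained-space means (one per model
#'   parameter).  Defaults correspond to natural-space sensitivities of 3,
#'   reward/punishment learning rates of 0.35/0.10 (0.2 when shared),
#'   lapse 0.15, action bias 0.6, approach and avoidance biases 1.
#' @param population_sds Named positive unconstrained-space SDs; default 1
#'   for every parameter.
#' @param effect_avoidance_group,effect_avoidance_threat_potentiation
#'   Unconstrained-space shifts of the avoidance-bias mean (see above);
#'   default 0.5 each.
#' @param within_subject_correlation Correlation, per parameter, between a
#'   subject's safe and threat values in unconstrained space.  The same
#'   participant performs both conditions, so parameters behave as stable
#'   subject traits modulated by condition; the default 0.7 mirrors
#'   typical test-retest reliability of learning-model parameters.  Set to
#'   0 for fully independent condition draws.
#' @param seed Integer seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_group = 20L,
                        model = winning_model(),
                        population_means = NULL,
                        population_sds = NULL,
                        effect_avoidance_group = 0.5,
                        effect_avoidance_threat_potentiation = 0.5,
                        within_subject_correlation = 0.7,
                        seed = 1L) {
  stopifnot(inherits(model, "gng_model"))
  if (n_per_group < 1L)
    stop_avoidrl("n_per_group must be >= 1", "avoidrl_spec_error")
  if (is.null(population_means))
    population_means <- default_population_means(model)
  if (is.null(population_sds))
    population_sds <- stats::setNames(rep(1, model$np), model$params)
  population_means <- as_param_vector(model, population_means)
  population_sds <- as_param_vector(model, population_sds)
  if (any(population_sds <= 0))
    stop_avoidrl("population_sds must be positive", "avoidrl_spec_error")
  if (within_subject_correlation < 0 || within_subject_correlation >= 1)
    stop_avoidrl("within_subject_correlation must lie in [0, 1)",
                 "avoidrl_spec_error")
  structure(list(
    n_per_group = as.integer(n_per_group), model = model,
    population_means = population_means, population_sds = population_sds,
    effect_avoidance_group = effect_avoidance_group,
    effect_avoidance_threat_potentiation = effect_avoidance_threat_potentiation,
    within_subject_correlation = within_subject_correlation,
    seed = as.integer(seed)), class = "cohort_spec")
}

# Unconstrained-space default population means for any of the variants.
# Learning about rewards and punishments proceeds at different speeds in
# the generating population (0.35 vs 0.10): the asymmetry the winning
# model's separate learning rates exist to capture.
default_population_means <- function(model) {
  nat <- c(reward_sensitivity = 3, punishment_sensitivity = 3,
           sensitivity = 3, learning_rate = 0.2,
           learning_rate_reward = 0.35, learning_rate_punishment = 0.1,
           lapse = 0.15, action_bias = 0.6,
           approach_bias = 1, avoidance_bias = 1, approach_avoid_bias = 1)
  to_unconstrained(model, nat[model$params])
}

# Population mean vector for one (group, condition) cell.
cell_population_mean <- function(spec, group, condition) {
  mu <- spec$population_means
  bias_name <- intersect(c("avoidance_bias", "approach_avoid_bias"),
                         spec$model$params)[1]
  if (!is.na(bias_name) && group == "anx") {
    mu[bias_name] <- mu[bias_name] + spec$effect_avoidance_group
    if (condition == "threat")
      mu[bias_name] <- mu[bias_name] + spec$effect_avoidance_threat_potentiation
  }
  mu
}

#' Generate a synthetic two-group cohort of task sessions
#'
#' Draws per-subject-condition parameters from the populations described by
#' `spec`, builds a fresh schedule per subject and simulates each
#' condition's half of the schedule with [simulate_agent()].  Each
#' parameter is decomposed into a stable subject component plus a
#' condition-specific deviation so that a subject's safe and threat values
#' correlate at `within_subject_correlation` while keeping the marginal
#' cell populations Gaussian with the specified means and SDs.  Conditions
#' enter only through their parameter populations (shock events do not
#' touch the latent state).
#'
#' @param spec A [cohort_spec()].
#' @param design A [task_design()].
#' @return Data frame of trial records (columns `subject_id`, `group`,
#'   `condition`, `block_index`, `trial_index`, `stimulus`, `action`,
#'   `feedback_shown`, `reinforcement`, `correct`), with the generative
#'   truth attached as attribute `"generative_params"` (one row per
#'   subject-condition, unconstrained space).
#' @export
generate_cohort <- function(spec = cohort_spec(), design = task_design()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(design, "task_design"))
  model <- spec$model
  with_seed(derive_seed(spec$seed, "cohort"), {
    groups <- c("control", "anx")
    rows <- list()
    truth <- list()
    for (g in groups) {
      for (i in seq_len(spec$n_per_group)) {
        subj <- sprintf("%s%02d", if (g == "control") "hc" else "anx", i)
        sched <- build_session_schedule(design,
                                        seed = stats::runif(1, 1, 2^30))
        rho <- spec$within_subject_correlation
        subj_dev <- stats::rnorm(model$np, 0,
                                 sqrt(rho) * spec$population_sds)
        for (cond in c("safe", "threat")) {
          mu <- cell_population_mean(spec, g, cond)
          theta_u <- mu + subj_dev +
            stats::rnorm(model$np, 0, sqrt(1 - rho) * spec$population_sds)
          names(theta_u) <- model$params
          nat <- to_natural(model, theta_u)
          half <- sched[sched$condition == cond, , drop = FALSE]
          tr <- simulate_agent(half, model, nat,
                               seed = stats::runif(1, 1, 2^30),
                               contingency = design$feedback_contingency)
          tr <- cbind(subject_id = subj, group = g, tr,
                      stringsAsFactors = FALSE)
          tr$condition <- cond
          rows[[length(rows) + 1L]] <- tr
          truth[[length(truth) + 1L]] <- data.frame(
            subject_id = subj, group = g, condition = cond,
            t(theta_u), stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    tp <- do.call(rbind, truth)
    rownames(tp) <- NULL
    attr(out, "generative_params") <- tp
    out
  })
}
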
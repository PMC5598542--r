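# Shared fixtures and independent oracles, all built in code.

# A natural-space parameter vector for the winning 8-parameter model.
winning_params <- function(reward_sensitivity = 3, punishment_sensitivity = 3,
                           learning_rate_reward = 0.2,
                           learning_rate_punishment = 0.2, lapse = 0.15,
                           action_bias = 0.6, approach_bias = 1.5,
                           avoidance_bias = 1.5) {
  c(reward_sensitivity = reward_sensitivity,
    punishment_sensitivity = punishment_sensitivity,
    learning_rate_reward = learning_rate_reward,
    learning_rate_punishment = learning_rate_punishment,
    lapse = lapse, action_bias = action_bias,
    approach_bias = approach_bias, avoidance_bias = avoidance_bias)
}

# Independent step-by-step session log-likelihood built from the exported
# single-trial operations; the C++ kernel never touches this path.
trace_loglik <- function(trials, params, spec) {
  state <- init_latent_state()
  ll <- 0
  for (t in seq_len(nrow(trials))) {
    w <- action_weights(state, trials$stimulus[t], params, spec)
    p <- action_probabilities(w["go"], w["nogo"], unname(params["lapse"]))
    ll <- ll + log(p[trials$action[t]])
    state <- update_latents(state, trials$stimulus[t], trials$action[t],
                            trials$reinforcement[t], params, spec)
  }
  unname(ll)
}

# Ten hand-laid trials covering all stimuli, both actions and all
# reinforcement codes.
ten_trial_fixture <- function() {
  data.frame(
    stimulus = c("GW", "GA", "NGW", "NGAL", "GW", "GA", "NGW", "NGAL",
                 "GW", "GA"),
    action = c("go", "nogo", "go", "nogo", "nogo", "go", "nogo", "go",
               "go", "go"),
    reinforcement = c(1L, -1L, 0L, 0L, 0L, -1L, 1L, -1L, 1L, 0L),
    stringsAsFactors = FALSE)
}

# Log-likelihood of k successes in n Bernoulli trials, logit-parameterized:
# the 1-parameter toy model used against grid-quadrature oracles.
bernoulli_loglik <- function(k, n) {
  function(x) {
    p <- stats::plogis(x[1])
    k * log(p) + (n - k) * log(1 - p)
  }
}

# Dense-grid oracles for 1-parameter posteriors and evidence.
grid_posterior_moments <- function(loglik, prior_mean, prior_var,
                                   lo = -8, hi = 8, n_grid = 20001) {
  x <- seq(lo, hi, length.out = n_grid)
  lp <- vapply(x, loglik, 0) +
    stats::dnorm(x, prior_mean, sqrt(prior_var), log = TRUE)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  mu <- sum(w * x)
  list(mean = mu, var = sum(w * (x - mu)^2))
}

grid_log_evidence <- function(loglik, prior_mean, prior_var,
                              lo = -8, hi = 8, n_grid = 20001) {
  x <- seq(lo, hi, length.out = n_grid)
  dx <- x[2] - x[1]
  lp <- vapply(x, loglik, 0) +
    stats::dnorm(x, prior_mean, sqrt(prior_var), log = TRUE)
  m <- max(lp)
  m + log(sum(exp(lp - m)) * dx)
}

# Small cohort generated under one shared population (no group effects).
null_cohort <- function(n_per_group = 4, seed = 1) {
  generate_cohort(cohort_spec(n_per_group = n_per_group,
                              effect_avoidance_group = 0,
                              effect_avoidance_threat_potentiation = 0,
                              seed = seed))
}

# Minimal gng_em_fit-shaped object whose "posterior modes" are given
# unconstrained parameter values (e.g. generative truth).
fit_from_params <- function(param_table, model) {
  posteriors <- lapply(seq_len(nrow(param_table)), function(i) {
    mode <- unlist(param_table[i, model$params])
    list(unit_id = paste(param_table$subject_id[i], param_table$condition[i],
                         sep = ":"),
         mode = mode, mode_natural = to_natural(model, mode),
         log_posterior = NA_real_, failed = FALSE)
  })
  structure(list(model = model, posteriors = posteriors,
                 units_meta = data.frame(
                   unit_id = vapply(posteriors, `[[`, "", "unit_id"),
                   subject_id = param_table$subject_id,
                   group = param_table$group,
                   condition = param_table$condition,
                   n_trials = NA_integer_, stringsAsFactors = FALSE)),
            class = "gng_em_fit")
}

quick_config <- function(...) {
  args <- utils::modifyList(
    list(max_iterations = 6L, convergence_tolerance = 0.05,
         n_random_restarts = 2L, seed = 1L, n_mc_samples = 300L), list(...))
  do.call(em_config, args)
}
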
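#' Model variants for the approach-avoidance go/no-go task
#'
#' Seven Rescorla-Wagner-family models are considered, built around a
#' six-parameter "standard" model (reward and punishment sensitivity, a
#' shared learning rate, a lapse, a general go/action bias and a single
#' Pavlovian approach-avoid bias) by adding or removing components:
#' dropping the action bias or the Pavlovian bias, collapsing the two
#' sensitivities into one, splitting the Pavlovian bias into separate
#' approach and avoidance biases, and splitting the learning rate into
#' separate reward and punishment learning rates.
#'
#' @return A named list of seven `gng_model` objects.
#' @seealso [gng_model()] for a single variant by name,
#'   [random_responder()] for the zero-parameter baseline.
#' @export
#' @examples
#' vapply(list_model_specs(), function(m) m$np, integer(1))
list_model_specs <- function() {
  defs <- list(
    list(name = "standard - action bias",
         has_action_bias = FALSE, has_approach_avoid = TRUE,
         separate_approach_avoid = FALSE, single_sensitivity = FALSE,
         separate_learning_rates = FALSE),
    list(name = "standard - approach-avoid",
         has_action_bias = TRUE, has_approach_avoid = FALSE,
         separate_approach_avoid = FALSE, single_sensitivity = FALSE,
         separate_learning_rates = FALSE),
    list(name = "standard + 2 approach-avoid - 1 sense",
         has_action_bias = TRUE, has_approach_avoid = TRUE,
         separate_approach_avoid = TRUE, single_sensitivity = TRUE,
         separate_learning_rates = FALSE),
    list(name = "standard",
         has_action_bias = TRUE, has_approach_avoid = TRUE,
         separate_approach_avoid = FALSE, single_sensitivity = FALSE,
         separate_learning_rates = FALSE),
    list(name = "standard + 2 approach-avoid",
         has_action_bias = TRUE, has_approach_avoid = TRUE,
         separate_approach_avoid = TRUE, single_sensitivity = FALSE,
         separate_learning_rates = FALSE),
    list(name = "standard + 2 learning rates",
         has_action_bias = TRUE, has_approach_avoid = TRUE,
         separate_approach_avoid = FALSE, single_sensitivity = FALSE,
         separate_learning_rates = TRUE),
    list(name = "standard + 2 approach-avoid + 2 learning rates",
         has_action_bias = TRUE, has_approach_avoid = TRUE,
         separate_approach_avoid = TRUE, single_sensitivity = FALSE,
         separate_learning_rates = TRUE)
  )
  specs <- lapply(defs, function(d) {
    d$params <- model_param_names(d)
    d$np <- length(d$params)
    d$random <- FALSE
    structure(d, class = "gng_model")
  })
  names(specs) <- vapply(specs, function(m) m$name, character(1))
  specs
}

# Free-parameter names implied by a variant's structural flags.
model_param_names <- function(d) {
  p <- if (d$single_sensitivity) "sensitivity" else
    c("reward_sensitivity", "punishment_sensitivity")
  p <- c(p, if (d$separate_learning_rates)
    c("learning_rate_reward", "learning_rate_punishment") else "learning_rate")
  p <- c(p, "lapse")
  if (d$has_action_bias) p <- c(p, "action_bias")
  if (d$has_approach_avoid) {
    p <- c(p, if (d$separate_approach_avoid)
      c("approach_bias", "avoidance_bias") else "approach_avoid_bias")
  }
  p
}

#' Retrieve one model variant by name
#'
#' @param name One of the seven variant names, as returned by
#'   `names(list_model_specs())`.  Matching is case-insensitive.
#' @return A `gng_model` object.
#' @export
gng_model <- function(name) {
  specs <- list_model_specs()
  hit <- match(tolower(trimws(name)), tolower(names(specs)))
  if (is.na(hit))
    stop_avoidrl(sprintf(
      "unknown model name '%s'; valid names are:\n  %s",
      name, paste(names(specs), collapse = "\n  ")), "avoidrl_spec_error")
  specs[[hit]]
}

#' The winning eight-parameter model variant
#'
#' Convenience accessor for "standard + 2 approach-avoid + 2 learning
#' rates": separate reward/punishment sensitivities and learning rates,
#' lapse, action bias, and separate Pavlovian approach and avoidance biases.
#' @return A `gng_model` object.
#' @export
winning_model <- function() {
  gng_model("standard + 2 approach-avoid + 2 learning rates")
}

#' Zero-parameter random-responder baseline
#'
#' Emits go and nogo with probability 1/2 on every trial regardless of
#' history; its session log-likelihood is exactly `n * log(0.5)`.  Used as
#' an analytic baseline for evidence and iBIC computations; not one of the
#' seven fitted variants.
#' @return A `gng_model` object with zero free parameters.
#' @export
random_responder <- function() {
  structure(list(name = "random responder", params = character(0), np = 0L,
                 has_action_bias = FALSE, has_approach_avoid = FALSE,
                 separate_approach_avoid = FALSE, single_sensitivity = FALSE,
                 separate_learning_rates = FALSE, random = TRUE),
            class = "gng_model")
}

#' @export
print.gng_model <- function(x, ...) {
  cat(sprintf("<gng_model> %s (%d free parameters)\n", x$name, x$np))
  if (x$np > 0) cat("  ", paste(x$params, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---- parameter transforms ---------------------------------------------------

# Sensitivities and Pavlovian biases are positive (exponential transform);
# learning rates, lapse and action bias lie in (0,1) (sigmoid transform).
PARAM_TRANSFORMS <- c(
  reward_sensitivity = "exp", punishment_sensitivity = "exp",
  sensitivity = "exp", approach_bias = "exp", avoidance_bias = "exp",
  approach_avoid_bias = "exp",
  learning_rate = "sigmoid", learning_rate_reward = "sigmoid",
  learning_rate_punishment = "sigmoid", lapse = "sigmoid",
  action_bias = "sigmoid")

#' Map unconstrained fitting-space parameters to natural space
#'
#' Fitting is done on the whole real line; natural-space parameters are
#' obtained with `exp` for sensitivities and Pavlovian biases and the
#' logistic sigmoid for learning rates, lapse and action bias.
#'
#' @param spec A `gng_model`.
#' @param x Named or unnamed numeric vector of length `spec$np` in
#'   unconstrained space (order `spec$params` when unnamed).
#' @return Named numeric vector in natural space.
#' @export
to_natural <- function(spec, x) {
  x <- as_param_vector(spec, x)
  tr <- PARAM_TRANSFORMS[names(x)]
  out <- x
  out[tr == "exp"] <- exp(x[tr == "exp"])
  out[tr == "sigmoid"] <- stats::plogis(x[tr == "sigmoid"])
  out
}

#' Inverse of [to_natural()]
#' @inheritParams to_natural
#' @param x Named or unnamed numeric vector in natural space.
#' @return Named numeric vector in unconstrained space.
#' @export
to_unconstrained <- function(spec, x) {
  x <- as_param_vector(spec, x)
  tr <- PARAM_TRANSFORMS[names(x)]
  out <- x
  out[tr == "exp"] <- log(x[tr == "exp"])
  out[tr == "sigmoid"] <- stats::qlogis(x[tr == "sigmoid"])
  out
}

as_param_vector <- function(spec, x) {
  if (length(x) != spec$np)
    stop_avoidrl(sprintf("model '%s' expects %d parameters, got %d",
                         spec$name, spec$np, length(x)), "avoidrl_spec_error")
  if (is.null(names(x))) names(x) <- spec$params
  else if (!setequal(names(x), spec$params))
    stop_avoidrl(sprintf("parameter names do not match model '%s': %s",
                         spec$name, paste(spec$params, collapse = ", ")),
                 "avoidrl_spec_error")
  x[spec$params]
}

# Expand a natural-space free-parameter vector to the canonical full
# 8-vector consumed by the likelihood kernel, resolving tied parameters.
expand_theta <- function(spec, natural) {
  natural <- as_param_vector(spec, natural)
  g <- function(nm) unname(natural[nm])
  rho_rew <- if (spec$single_sensitivity) g("sensitivity") else
    g("reward_sensitivity")
  rho_pun <- if (spec$single_sensitivity) g("sensitivity") else
    g("punishment_sensitivity")
  lr_rew <- if (spec$separate_learning_rates) g("learning_rate_reward") else
    g("learning_rate")
  lr_pun <- if (spec$separate_learning_rates)
    g("learning_rate_punishment") else g("learning_rate")
  app <- avo <- 0
  if (spec$has_approach_avoid) {
    app <- if (spec$separate_approach_avoid) g("approach_bias") else
      g("approach_avoid_bias")
    avo <- if (spec$separate_approach_avoid) g("avoidance_bias") else
      g("approach_avoid_bias")
  }
  list(theta = c(rho_rew, rho_pun, lr_rew, lr_pun, g("lapse"),
                 if (spec$has_action_bias) g("action_bias") else 0, app, avo),
       has_action_bias = spec$has_action_bias,
       has_appavo = spec$has_approach_avoid)
}

# ---- task vocabulary --------------------------------------------------------

STIMULI <- c("GW", "GA", "NGW", "NGAL")

#' Stimulus valence and required action
#'
#' `stimulus_valence` returns "win" for go-to-win (GW) and no-go-to-win
#' (NGW) stimuli and "avoid" for go-to-avoid (GA) and no-go-to-avoid (NGAL)
#' stimuli; `required_action` returns the instrumentally correct action.
#' @param stimulus Character vector of stimulus codes.
#' @return Character vector.
#' @export
stimulus_valence <- function(stimulus) {
  check_stimulus(stimulus)
  ifelse(stimulus %in% c("GW", "NGW"), "win", "avoid")
}

#' @rdname stimulus_valence
#' @export
required_action <- function(stimulus) {
  check_stimulus(stimulus)
  ifelse(stimulus %in% c("GW", "GA"), "go", "nogo")
}

check_stimulus <- function(stimulus) {
  bad <- !(stimulus %in% STIMULI)
  if (any(bad))
    stop_avoidrl(sprintf("unknown stimulus label(s): %s",
                         paste(unique(stimulus[bad]), collapse = ", ")),
                 "avoidrl_parse_error")
  invisible(stimulus)
}

# ---- latent state and single-trial operations ------------------------------

#' Fresh latent state for one learning session
#'
#' Q values for both actions and the Pavlovian stimulus values all start at
#' exactly zero.
#' @return A list with matrix `q` (actions x stimuli) and vector `v`.
#' @export
init_latent_state <- function() {
  list(q = matrix(0, nrow = 2, ncol = 4,
                  dimnames = list(c("go", "nogo"), STIMULI)),
       v = stats::setNames(numeric(4), STIMULI))
}

#' Rescorla-Wagner update of the latent state after one trial
#'
#' Moves the chosen action's Q value and the stimulus value toward
#' `sensitivity * reinforcement` by a fraction equal to the learning rate,
#' using the sensitivity and learning rate matching the trial's valence
#' (win stimuli use the reward pair, avoid stimuli the punishment pair).
#'
#' @param state Latent state from [init_latent_state()] or a prior update.
#' @param stimulus One of "GW", "GA", "NGW", "NGAL".
#' @param action "go" or "nogo".
#' @param reinforcement Integer in -1, 0, +1.
#' @param params Natural-space parameter vector for `spec`.
#' @param spec A `gng_model`.
#' @return The updated latent state.
#' @export
update_latents <- function(state, stimulus, action, reinforcement, params,
                           spec) {
  check_stimulus(stimulus)
  stopifnot(action %in% c("go", "nogo"), reinforcement %in% c(-1L, 0L, 1L))
  ex <- expand_theta(spec, params)
  win <- stimulus_valence(stimulus) == "win"
  sens <- if (win) ex$theta[1] else ex$theta[2]
  lr <- if (win) ex$theta[3] else ex$theta[4]
  target <- sens * reinforcement
  state$q[action, stimulus] <- state$q[action, stimulus] +
    lr * (target - state$q[action, stimulus])
  state$v[stimulus] <- state$v[stimulus] + lr * (target - state$v[stimulus])
  state
}

#' Action weights for one stimulus
#'
#' The nogo weight is the nogo Q value.  The go weight adds to the go Q
#' value the static action bias (when the model has one) and the Pavlovian
#' term: the stimulus value scaled by the approach bias on win stimuli and
#' by the avoidance bias on avoid stimuli, so that negatively valued avoid
#' stimuli suppress responding and positively valued win stimuli promote it.
#'
#' @inheritParams update_latents
#' @return Named numeric vector `c(go = , nogo = )`.
#' @export
action_weights <- function(state, stimulus, params, spec) {
  check_stimulus(stimulus)
  ex <- expand_theta(spec, params)
  win <- stimulus_valence(stimulus) == "win"
  w_go <- state$q["go", stimulus]
  if (ex$has_action_bias) w_go <- w_go + ex$theta[6]
  if (ex$has_appavo)
    w_go <- w_go + (if (win) ex$theta[7] else ex$theta[8]) * state$v[stimulus]
  c(go = unname(w_go), nogo = unname(state$q["nogo", stimulus]))
}

#' Lapse-squashed softmax choice probabilities
#'
#' `p = softmax(weights) * (1 - lapse) + lapse / 2`, so both action
#' probabilities lie in `[lapse/2, 1 - lapse/2]` and sum to one.
#'
#' @param weight_go,weight_nogo Action weights.
#' @param lapse Lapse probability in `[0, 1]`.
#' @return Named numeric vector `c(go = , nogo = )`.
#' @export
action_probabilities <- function(weight_go, weight_nogo, lapse) {
  if (!is.numeric(lapse) || lapse < 0 || lapse > 1)
    stop_avoidrl("lapse must lie in [0, 1]", "avoidrl_domain_error")
  p_go <- stats::plogis(weight_go - weight_nogo) * (1 - lapse) + lapse / 2
  c(go = unname(p_go), nogo = unname(1 - p_go))
}

# ---- session likelihood -----------------------------------------------------

#' Log-likelihood of one subject-condition session
#'
#' Sums the log probability of each recorded action over trials in
#' presentation order, updating the latent state after every trial with the
#' recorded reinforcement.  The empty session has log-likelihood 0.
#'
#' @param trials Data frame with columns `stimulus`, `action`,
#'   `reinforcement`, ordered by presentation.
#' @param params Natural-space parameter vector for `spec` (ignored for the
#'   random responder).
#' @param spec A `gng_model`.
#' @return A single finite number (finite whenever lapse > 0), always <= 0.
#' @export
session_loglik <- function(trials, params, spec) {
  n <- nrow(trials)
  if (n == 0L) return(0)
  if (isTRUE(spec$random)) return(n * log(0.5))
  enc <- encode_trials(trials)
  ex <- expand_theta(spec, params)
  gng_session_loglik_cpp(enc$stimulus, enc$action, enc$reinforcement,
                         ex$theta, ex$has_action_bias, ex$has_appavo)
}

# Integer encoding shared with the C++ kernel.
encode_trials <- function(trials) {
  need <- c("stimulus", "action", "reinforcement")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop_avoidrl(paste("missing trial column(s):",
                       paste(miss, collapse = ", ")), "avoidrl_parse_error")
  check_stimulus(trials$stimulus)
  if (!all(trials$action %in% c("go", "nogo")))
    stop_avoidrl("action must be 'go' or 'nogo'", "avoidrl_parse_error")
  r <- trials$reinforcement
  if (!all(r %in% c(-1L, 0L, 1L)))
    stop_avoidrl("reinforcement must be -1, 0 or +1", "avoidrl_parse_error")
  list(stimulus = match(trials$stimulus, STIMULI),
       action = as.integer(trials$action == "go"),
       reinforcement = as.integer(r))
}
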
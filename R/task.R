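#' Approach-avoidance task design
#'
#' Describes the structure of one session: 480 trials in 24 alternating
#' safe/threat blocks of 20 trials, each block containing five trials of
#' each of the four stimulus types (go-to-win, go-to-avoid, no-go-to-win,
#' no-go-to-avoid), probabilistic feedback delivering the scheduled
#' probable outcome on 80% of trials, and a single unpredictable shock in
#' one third of the threat blocks (four shocks in total).  Points are a
#' display convention only (+10 / -10); the learning models see
#' reinforcements coded +1 / -1 / 0.
#'
#' @param n_blocks Total number of blocks; must be even so safe and threat
#'   blocks can strictly alternate.
#' @param trials_per_block Trials per block; must be divisible by 4 so the
#'   stimulus types occur in equal numbers within every block.
#' @param feedback_contingency Probability that the scheduled probable
#'   outcome is delivered; strictly between 0 and 1.
#' @param shock_block_fraction Fraction of threat blocks carrying a shock.
#' @param points_win,points_loss Displayed point values (not used by the
#'   models).
#' @return A `task_design` object.
#' @export
#' @examples
#' d <- task_design()
#' d$n_trials  # 480
task_design <- function(n_blocks = 24L, trials_per_block = 20L,
                        feedback_contingency = 0.8,
                        shock_block_fraction = 1 / 3,
                        points_win = 10L, points_loss = -10L) {
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  if (n_blocks < 2L || n_blocks %% 2L != 0L)
    stop_avoidrl("n_blocks must be an even number >= 2 so safe and threat blocks alternate",
                 "avoidrl_design_error")
  if (trials_per_block < 4L || trials_per_block %% 4L != 0L)
    stop_avoidrl("trials_per_block must be divisible by 4 (equal stimulus counts per block)",
                 "avoidrl_design_error")
  if (!(feedback_contingency > 0 && feedback_contingency < 1))
    stop_avoidrl("feedback_contingency must lie strictly between 0 and 1",
                 "avoidrl_design_error")
  if (shock_block_fraction < 0 || shock_block_fraction > 1)
    stop_avoidrl("shock_block_fraction must lie in [0, 1]",
                 "avoidrl_design_error")
  n_threat <- n_blocks %/% 2L
  structure(list(
    n_blocks = n_blocks, trials_per_block = trials_per_block,
    n_trials = n_blocks * trials_per_block,
    feedback_contingency = feedback_contingency,
    shock_block_fraction = shock_block_fraction,
    shocks_total = as.integer(round(shock_block_fraction * n_threat)),
    points_win = points_win, points_loss = points_loss
  ), class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf(
    "<task_design> %d trials: %d alternating safe/threat blocks x %d trials (%d per stimulus type)\n",
    x$n_trials, x$n_blocks, x$trials_per_block, x$trials_per_block %/% 4L))
  cat(sprintf("  feedback contingency %.2f; %d shock(s) across threat blocks\n",
              x$feedback_contingency, x$shocks_total))
  invisible(x)
}

#' Build the trial schedule for one session
#'
#' Blocks strictly alternate safe/threat (safe first); within every block
#' the four stimulus types appear in equal numbers in a random order.  A
#' randomly chosen third of the threat blocks (rounded) carry one shock
#' each; shocks mark the threat manipulation and do not enter the learning
#' models.
#'
#' @param design A [task_design()].
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @return Data frame with columns `block_index` (1-based), `condition`
#'   ("safe"/"threat"), `stimulus`, plus attribute `shock_blocks` (integer
#'   block indices carrying a shock).
#' @export
build_session_schedule <- function(design = task_design(), seed = 1L) {
  stopifnot(inherits(design, "task_design"))
  with_seed(derive_seed(seed, "schedule"), {
    per_stim <- design$trials_per_block %/% 4L
    blocks <- lapply(seq_len(design$n_blocks), function(b) {
      data.frame(
        block_index = b,
        condition = if (b %% 2L == 1L) "safe" else "threat",
        stimulus = sample(rep(STIMULI, per_stim)),
        stringsAsFactors = FALSE)
    })
    sched <- do.call(rbind, blocks)
    threat_blocks <- unique(sched$block_index[sched$condition == "threat"])
    n_shock <- as.integer(round(design$shock_block_fraction *
                                  length(threat_blocks)))
    shock_blocks <- sort(sample(threat_blocks, n_shock))
    attr(sched, "shock_blocks") <- shock_blocks
    sched
  })
}

#' Draw probabilistic feedback for one trial
#'
#' The scheduled probable outcome is the favourable one after a correct
#' choice and the unfavourable one after an incorrect choice; it is
#' delivered with probability `contingency` and the alternative otherwise.
#' Win stimuli (GW, NGW) emit reinforcements in \{+1, 0\} and avoid stimuli
#' (GA, NGAL) in \{-1, 0\}; a nonzero reinforcement corresponds to a
#' valenced outcome face on screen, a zero to the no-points display.
#'
#' @param stimulus Stimulus code.
#' @param action "go" or "nogo".
#' @param contingency Probability in (0, 1]; 1 makes the scheduled probable
#'   outcome certain.
#' @return List with integer `reinforcement` and logical `feedback_shown`
#'   (TRUE when a valenced face, i.e. nonzero reinforcement, is shown).
#'   Vectorised over `stimulus`/`action`.
#' @export
sample_feedback <- function(stimulus, action, contingency = 0.8) {
  if (!(all(contingency > 0) && all(contingency <= 1)))
    stop_avoidrl("contingency must lie in (0, 1]", "avoidrl_design_error")
  check_stimulus(stimulus)
  n <- length(stimulus)
  correct <- action == required_action(stimulus)
  win <- stimulus_valence(stimulus) == "win"
  probable <- stats::runif(n) < contingency
  favourable <- correct == probable  # favourable outcome delivered
  reinforcement <- integer(n)
  reinforcement[win & favourable] <- 1L       # reward face
  reinforcement[!win & !favourable] <- -1L    # punishment face
  list(reinforcement = reinforcement, feedback_shown = reinforcement != 0L)
}
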
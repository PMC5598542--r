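---
title: "Modelling Pavlovian avoidance in go/no-go behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Pavlovian avoidance in go/no-go behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avoidrl)
```

## The task and the scientific question

Avoidance — withholding action in the face of potentially negative
outcomes — is a core feature of mood and anxiety disorders.  `avoidrl`
implements a computational pipeline for studying it with an
approach-avoidance go/no-go task: four trial types cross the required
action (respond vs withhold) with outcome valence (win points vs avoid
losing points), so that on *go-to-win* (GW) and *no-go-to-avoid* (NGAL)
trials the prepotent Pavlovian response (approach appetitive cues, freeze
to aversive ones) is aligned with the instrumental requirement, while on
*go-to-avoid* (GA) and *no-go-to-win* (NGW) trials it must be overcome.
Sessions alternate *safe* and *threat* blocks; in threat blocks
unpredictable electric shocks may occur, inducing anxiety orthogonal to
the task.  The degree to which a participant's choices are captured by a
Pavlovian avoidance-bias parameter, and how that parameter shifts with
diagnostic group and with threat, is the scientific target.

The default `task_design()` uses 480 trials in 24 alternating blocks of
20 trials, five of each stimulus type per block.  Only the 480-trial
total, the strict alternation, the equal per-block stimulus counts, and
the four shocks (one in a third of the threat blocks) are fixed by the
task description; the 24 × 20 layout is the only integral layout
consistent with all of them, and is flagged here as an inference.
Feedback is probabilistic: the scheduled probable outcome (favourable
after a correct choice, unfavourable after an incorrect one) is delivered
with probability 0.8.  Win stimuli emit reinforcements in {+1, 0} and
avoid stimuli in {−1, 0}; the ±1 outcomes correspond to the valenced
feedback faces, 0 to the no-points display.  Shocks are recorded in the
schedule but do not enter the learning models: threat affects behaviour
only through condition-specific parameters, which is how the modelling
framework treats the manipulation.

## The model family

All seven variants are Rescorla-Wagner learners over action values
$Q(a, s)$ and Pavlovian stimulus values $V(s)$, both initialized at 0:

$$Q_t(a_t, s_t) = Q_{t-1}(a_t, s_t) + \epsilon\,[\rho\, r_t - Q_{t-1}(a_t, s_t)]$$
$$V_t(s_t) = V_{t-1}(s_t) + \epsilon\,[\rho\, r_t - V_{t-1}(s_t)]$$

with learning rate $\epsilon$, sensitivity $\rho$ (scaling the nominal
reinforcement $r_t \in \{+1, -1, 0\}$), both taken from the reward pair
on win stimuli and the punishment pair on avoid stimuli (trial valence,
not realized outcome sign).  $V$ updates on every trial, including
$r = 0$ trials.  The action weight adds a static action bias $b$ and the
Pavlovian term to the go side only:

$$W(go, s) = Q(go, s) + b + \pi_s V(s), \qquad W(nogo, s) = Q(nogo, s),$$

where $\pi_s$ is the approach bias on win stimuli and the avoidance bias
on avoid stimuli (a single shared value in the smaller variants).
Because $V(s) \le 0$ for avoid stimuli, a large avoidance bias suppresses
responding to them — the formalization of avoidance.  Choice
probabilities pass through a lapse-squashed softmax,

$$P(a \mid s) = \mathrm{softmax}(W)\,(1 - \xi) + \xi/2,$$

bounding both actions' probabilities in $[\xi/2, 1 - \xi/2]$.  The seven
variants add or remove the action bias, the Pavlovian bias, the second
sensitivity, the approach/avoid split, and the learning-rate split,
giving 5–8 free parameters; `list_model_specs()` enumerates them and
`winning_model()` returns the 8-parameter variant with separate
approach/avoidance biases and separate reward/punishment learning rates.

Parameters are fitted on the whole real line and mapped to their natural
ranges with `exp` (sensitivities, Pavlovian biases) or the logistic
sigmoid (learning rates, lapse, action bias).  The (0, 1) bound on the
action bias follows the printed model specification; it is unusual
relative to earlier work on this task, where the action bias is
unbounded, and it matters for identifiability (see *Limitations*).

## Hierarchical fitting

`run_em()` implements hierarchical type-II maximum-likelihood EM.  The
top level is an independent Gaussian per parameter in unconstrained
space.  Each E-step maximizes every unit's log-likelihood plus log prior
(a unit is one subject-condition session: every subject contributes a
safe and a threat unit), and Laplace-approximates the posterior with the
central-finite-difference Hessian (step $10^{-4}$) at the mode; the
M-step re-estimates the prior from the posterior moments, i.e.
mean of modes and mean of (mode² + posterior variance) minus squared
mean, floored at $10^{-6}$ and capped at 25 (a cap that is already
diffuse after the exponential transform and guards against near-singular
Hessians at unconverged modes).  The algorithm starts from per-unit
maximum-likelihood estimates; because unpenalized ML routinely drives
weakly identified parameters to the optimizer box, the initial prior
moments are computed from winsorized estimates (|x| ≤ 5).

The EM objective recorded in the trace — and used for the convergence
test — is the summed per-unit Laplace approximation to the log marginal
likelihood.  The summed posterior density at the mode is not comparable
across iterations (the prior changes), whereas the approximate marginal
likelihood is the quantity type-II ML ascends.  Laplace-EM guarantees
ascent only up to approximation error: on cohorts of 40+ units the trace
is monotone to within ~0.05 per step, while very small cohorts can show
dips of a few units; the tests assert bounded dips rather than strict
monotonicity.  Defaults (50 iterations, tolerance $10^{-3}$ on the
objective change, 5 optimizer starts per unit per E-step — one warm, the
rest drawn from the current prior) are recorded in every fit's
configuration; the optimizer is bounded L-BFGS-B on ±12, wide enough to
be inactive at any plausible mode.

## Model and prior-partition comparison

Four partition schemes assign the subject-condition units to top-level
priors: one per group × condition cell, one per condition, one per group,
or a single common prior.  Each (variant, scheme) pair is scored by the
integrated BIC: per cell, $-2 \sum_u \log \hat p(\mathrm{data}_u)$ plus a
penalty of two top-level quantities (mean and variance) per parameter
times $\log N$ (total trials in the cell), summed over cells.  The unit
evidence integral is approximated by prior Monte-Carlo with log-sum-exp
(default 2,000 draws, seed-controlled); on one-parameter toy problems the
estimate agrees with dense-grid quadrature to within 2%, which the test
suite checks.  `compare_models()` returns the full table with
$\Delta$iBIC and approximate Bayes factors $\exp(\Delta/2)$; the lowest
total wins.

## Synthetic cohorts

`generate_cohort()` is first-class, tested code, and defines the
conditions under which the pipeline is validated.  Per group ×
condition, unconstrained parameters are Gaussian with defaults chosen to
be realistic for this task family: sensitivities 3, reward/punishment
learning rates 0.35/0.10, lapse 0.15, action bias 0.6, Pavlovian biases
1 (natural scale), SD 1 per parameter in unconstrained space — spreads
of an order of magnitude or more on the exponential scales, matching the
wide subject spreads this task elicits.  The learning-rate asymmetry
reflects what the 8-parameter winning variant exists to capture: if the
population learned identically from rewards and punishments, its
shared-rate reduction would be the better description of every cohort
and model recovery would be meaningless.

Two further structural choices matter:

* **Within-subject reliability.**  A subject's safe and threat parameters
  share a stable subject component (correlation 0.7, in the range of
  test-retest reliabilities reported for learning-model parameters),
  with condition-specific deviations on top.  Fully independent draws
  would make threat-minus-safe difference scores carry the entire
  between-subject variance twice over, which no within-subject design
  implies.
* **Clinical effects.**  `effect_avoidance_group` shifts the anxiety
  group's log avoidance-bias mean in both conditions (default 0.5) and
  `effect_avoidance_threat_potentiation` adds a further shift under
  threat (default 0.5) — the diathesis-stress structure.  With both set
  to 0 the four populations are identical.

What the generator does *not* emulate: real response times, slow
non-stationarities (fatigue, attention), shock-evoked transients in
learning, and any within-subject correlation structure beyond the single
shared component.  Passing tests therefore demonstrate internal
consistency of the pipeline under the stated population model, not that
real data meet these assumptions.

## Posterior predictive checks and inference

`simulate_from_fit()` replays the task with agents set to each unit's
posterior-mode parameters (mode rather than mean or samples: the mode is
what the Laplace machinery localizes), with fresh random feedback by
default, and `pgo_curves()` / `accuracy_summary()` produce the standard
behavioural summaries (P(go) by stimulus-presentation position; accuracy
by trial type).  Group and condition effects on recovered parameters are
tested with two-tailed permutation tests (`parameter_group_tests()`):
group main effect on subject means, interaction as a between-group test
on threat-minus-safe difference scores, within-group condition effects by
sign-flipping paired differences.  Exhaustive enumeration is used
whenever the number of relabelings (or sign patterns) fits the
permutation budget, giving exact p values; Monte-Carlo mode uses the
add-one rule so p is never zero.  The default statistic is the mean
difference; no multiplicity correction is applied by default.

## Problem sizes used by the test suite

The validation suite works at desk scale, chosen to finish in minutes
while keeping each question answerable: parameter recovery uses 40 units
of 240 trials (the task's per-condition session length); model recovery
uses five replicate 40-unit cohorts with reduced Monte-Carlo sample
counts; the power demonstration uses five cohorts of 40 subjects per
group with strong effects (1.5 log-units); permutation calibration uses
1,000 null replications.

## Numerical choices and degenerate inputs

Transforms round-trip to 1e−10; the likelihood kernel evaluates the trial
log-probability in log space so extreme prior draws cannot underflow the
lapse mixture, and parameter draws that overflow to non-finite action
weights receive zero likelihood.  Empty sessions have log-likelihood 0;
an all-identical permutation input returns p = 1 with a warning; a
non-positive-definite Hessian is repaired to the nearest
positive-definite matrix (eigenvalue floor) and flagged.  All randomness
flows from named seeds; every stage restores the caller's RNG state.

## Known limitations

* **Action-bias identifiability.**  With the printed (0, 1) bound, the
  action bias contributes at most one unit to the go weight while
  sensitivity-scaled action values span several; at 240 trials per unit
  its per-unit posterior variance is of the same order as its population
  variance, so even optimally shrunken modes cannot correlate much above
  ~0.6 with the truth, and in practice recovery of this parameter is
  clearly weaker than for the other seven.  An unbounded action-bias
  variant would behave differently but is not the printed model.
* **Conservative parameter-level inference.**  Model comparison
  (correctly) selects the single common prior unless cohorts are very
  large, and testing group differences on parameters that were shrunk
  toward a common mean attenuates them several-fold.  Group main effects
  of the size generated here survive; the group × condition interaction
  on the avoidance bias is attenuated into the ~40%-power regime at 40
  subjects per group, so interaction detection through this pipeline
  should be expected to need substantially larger samples or a
  parameter-level partition comparison (testing the avoidance bias alone
  under multiple priors), which this package does not implement.
* **Evidence estimator.**  Prior Monte-Carlo is simple and honest but
  noisy for diffuse fitted priors; iBIC differences of a few nats between
  close variants should not be over-read at small sample counts.
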
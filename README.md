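# avoidrl

Reinforcement-learning modelling of Pavlovian avoidance in go/no-go
behaviour under threat of shock.

## What this package is for

Excessive avoidance is a core feature of mood and anxiety disorders, but
"avoidance" measured by self-report is hard to connect to mechanism.
This package operationalizes it inside a reinforcement-learning model of
an approach-avoidance go/no-go task: four trial types cross required
action (go / no-go) with outcome valence (win / avoid losing), under
alternating safe and threat-of-shock blocks.  A Pavlovian
**avoidance-bias** parameter couples aversive stimulus value to response
suppression; the scientific questions are whether that parameter is
elevated in a clinical group and further potentiated by threat.

The pipeline covers:

* **Task simulation** (`task_design()`, `build_session_schedule()`,
  `generate_cohort()`): 480 trials, 24 alternating safe/threat blocks,
  equal stimulus counts per block, 80%-contingent feedback, four shocks;
  synthetic two-group cohorts with known generative parameters.
* **Seven Rescorla-Wagner model variants** (`list_model_specs()`), built
  around a six-parameter "standard" model.  Latent updates
  `Q += ε(ρr − Q)`, `V += ε(ρr − V)`; go weight
  `Q(go,s) + b + π_s V(s)`; choice rule
  `softmax · (1 − ξ) + ξ/2` with lapse ξ.  The winning 8-parameter
  variant splits the Pavlovian bias into approach/avoidance and the
  learning rate into reward/punishment components.
* **Hierarchical type-II ML fitting** (`run_em()`, `fit_model()`):
  empirical-Bayes EM with per-unit Laplace approximations, units being
  subject-condition sessions.
* **Model and prior-partition selection** (`compare_models()`):
  integrated BIC over all variants × four population-prior partitions
  (by group × condition, by condition, by group, or one common prior),
  with approximate Bayes factors `exp(ΔiBIC/2)`.
* **Posterior predictive checks** (`simulate_from_fit()`,
  `pgo_curves()`, `accuracy_summary()`, `plot_pgo_curves()`).
* **Permutation inference** (`parameter_group_tests()`): two-tailed
  group, condition and interaction tests on recovered parameters.
* **A driver** (`run_pipeline()`) tying the stages together from a
  nested-list or YAML configuration, with CSV trial-table I/O
  (`read_trials()` / `write_trials()`).

## Worked example

Simulate a small two-group cohort with elevated, threat-potentiated
avoidance in the clinical group, fit the winning model under a single
population prior, and test the avoidance-bias parameter:

```r
library(avoidrl)

coh <- generate_cohort(cohort_spec(n_per_group = 8,
                                   effect_avoidance_group = 1,
                                   effect_avoidance_threat_potentiation = 1,
                                   seed = 42))
nrow(coh)
#> [1] 7680

fit <- fit_model(coh, winning_model(), "one_dist",
                 em_config(max_iterations = 10, convergence_tolerance = 0.05,
                           n_random_restarts = 2, seed = 7))
fit
#> <gng_fit> model 'standard + 2 approach-avoid + 2 learning rates', scheme one_dist: iBIC = 7522.2

pt <- fit_parameter_table(fit)
round(tapply(pt$avoidance_bias, list(pt$group, pt$condition), mean), 3)
#>          safe threat
#> anx     1.910  3.478
#> control 1.759  1.449

tests <- parameter_group_tests(fit, "avoidance_bias",
                               n_permutations = 5000, seed = 7)
tests$group_main$p_two_tailed   #> 0.0562
tests$interaction$p_two_tailed  #> 0.0394
```

The cell means show the generated structure after fitting: the anxiety
group's avoidance bias rises under threat (1.91 → 3.48) while the
control group's does not, and the permutation test flags the
group × condition interaction (p ≈ .04) with the group main effect at
the margin (p ≈ .056) at this small n.  Note that fitting under one
common prior shrinks all units toward a single mean, so parameter-level
tests run conservative; the methods vignette
(`vignettes/avoidance-modelling.Rmd`) discusses this and every other
modelling choice in detail.

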
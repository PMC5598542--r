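test_that("the seven variants and their parameter counts match the suite", {
  specs <- list_model_specs()
  expect_length(specs, 7L)
  np <- vapply(specs, function(m) m$np, integer(1))
  expect_equal(unname(np), c(5L, 5L, 6L, 6L, 7L, 7L, 8L))
  expect_equal(sum(np), 44L)
  expect_equal(gng_model("standard")$np, 6L)
  expect_equal(winning_model()$np, 8L)
  expect_equal(gng_model("STANDARD")$name, "standard")  # case-insensitive
  expect_error(gng_model("no such model"), class = "avoidrl_spec_error")
  # flags and parameter lists are consistent
  for (m in specs) {
    expect_equal(length(m$params), m$np)
    expect_equal("action_bias" %in% m$params, m$has_action_bias)
    expect_equal(any(c("approach_bias", "avoidance_bias",
                       "approach_avoid_bias") %in% m$params),
                 m$has_approach_avoid)
  }
})

test_that("parameter transforms are correct and round-trip", {
  m <- winning_model()
  nat <- to_natural(m, rep(0, 8))
  # sigmoid-transformed parameters map 0 -> 0.5, exp-transformed 0 -> 1
  expect_equal(unname(nat[c("lapse", "action_bias", "learning_rate_reward")]),
               rep(0.5, 3))
  expect_equal(unname(nat[c("reward_sensitivity", "avoidance_bias")]),
               rep(1, 2))
  set.seed(3)
  for (m in list_model_specs()) {
    x <- rnorm(m$np, 0, 2)
    expect_equal(to_unconstrained(m, to_natural(m, x)),
                 stats::setNames(x, m$params), tolerance = 1e-10)
    expect_true(all(to_natural(m, x) > 0))
  }
  expect_error(to_natural(winning_model(), rep(0, 5)),
               class = "avoidrl_spec_error")
})

test_that("latent-state updates follow the Rescorla-Wagner rule", {
  m <- gng_model("standard")
  p <- c(reward_sensitivity = 2, punishment_sensitivity = 2,
         learning_rate = 0.5, lapse = 0.1, action_bias = 0.5,
         approach_avoid_bias = 1)
  st <- init_latent_state()
  expect_true(all(st$q == 0) && all(st$v == 0))
  # Q = 0, lr = .5, sens = 2, r = +1 -> Q' = 1, Value' = 1
  st1 <- update_latents(st, "GW", "go", 1L, p, m)
  expect_equal(unname(st1$q["go", "GW"]), 1)
  expect_equal(unname(st1$v["GW"]), 1)
  # only the chosen action's Q and that stimulus's value change
  st1$q["go", "GW"] <- 0; st1$v["GW"] <- 0
  expect_equal(st1, st)
  # zero prediction error: sens * r == Q leaves Q unchanged
  st2 <- init_latent_state()
  st2$q["go", "GW"] <- 2; st2$v["GW"] <- 2
  st3 <- update_latents(st2, "GW", "go", 1L, p, m)
  expect_equal(st3, st2)
  # lr = 0 freezes the state for any reinforcement
  p0 <- replace(p, "learning_rate", 0)
  for (r in c(-1L, 0L, 1L))
    expect_equal(update_latents(st2, "GA", "nogo", r, p0, m), st2)
  # punishment parameters drive avoid-stimulus updates
  p2 <- winning_params(punishment_sensitivity = 4,
                       learning_rate_punishment = 0.25)
  st4 <- update_latents(init_latent_state(), "GA", "go", -1L, p2,
                        winning_model())
  expect_equal(unname(st4$q["go", "GA"]), 0.25 * (4 * -1))
})

test_that("action weights combine Q, action bias and the Pavlovian term", {
  m <- winning_model()
  p <- winning_params(action_bias = 0.2, avoidance_bias = 2,
                      approach_bias = 1.5)
  st <- init_latent_state()
  st$q["go", "GA"] <- 0.3
  st$v["GA"] <- -0.4
  w <- action_weights(st, "GA", p, m)
  expect_equal(unname(w["go"]), 0.3 + 0.2 + 2 * (-0.4))  # -0.3
  expect_equal(unname(w["nogo"]), 0)
  # with Value = 0 the go-nogo difference is bias-independent
  st$v["GA"] <- 0
  w1 <- action_weights(st, "GA", p, m)
  w2 <- action_weights(st, "GA", replace(p, "avoidance_bias", 50), m)
  expect_equal(w1["go"] - w1["nogo"], w2["go"] - w2["nogo"])
  # approach bias applies on win stimuli
  st$v["GW"] <- 0.5
  w3 <- action_weights(st, "GW", p, m)
  expect_equal(unname(w3["go"]), 0.2 + 1.5 * 0.5)
  # no action bias model, zero state -> both weights zero
  m0 <- gng_model("standard - action bias")
  p0 <- c(reward_sensitivity = 1, punishment_sensitivity = 1,
          learning_rate = 0.2, lapse = 0.1, approach_avoid_bias = 1)
  w0 <- action_weights(init_latent_state(), "NGW", p0, m0)
  expect_equal(unname(w0), c(0, 0))
})

test_that("squashed softmax probabilities behave as specified", {
  expect_equal(unname(action_probabilities(5, -3, 1)), c(0.5, 0.5))
  expect_equal(unname(action_probabilities(1.3, 1.3, 0)), c(0.5, 0.5))
  expect_equal(unname(action_probabilities(log(3), 0, 0)["go"]), 0.75,
               tolerance = 1e-12)
  set.seed(4)
  for (i in 1:50) {
    p <- action_probabilities(rnorm(1, 0, 3), rnorm(1, 0, 3), runif(1))
    expect_equal(unname(sum(p)), 1, tolerance = 1e-12)
  }
  lapse <- 0.3
  p <- action_probabilities(100, -100, lapse)
  expect_equal(unname(p), c(1 - lapse / 2, lapse / 2))
  expect_error(action_probabilities(0, 0, 1.2), class = "avoidrl_domain_error")
})

test_that("session log-likelihood matches an independent trial-by-trial trace", {
  tr <- ten_trial_fixture()
  for (m in list_model_specs()) {
    set.seed(m$np)
    p <- to_natural(m, rnorm(m$np))
    expect_equal(session_loglik(tr, p, m), trace_loglik(tr, p, m),
                 tolerance = 1e-12, info = m$name)
  }
  # longer randomized session, winning model
  sch <- build_session_schedule(task_design(), seed = 5)
  long <- simulate_agent(sch[sch$condition == "safe", ], winning_model(),
                         winning_params(), seed = 6)
  expect_equal(session_loglik(long, winning_params(), winning_model()),
               trace_loglik(long, winning_params(), winning_model()),
               tolerance = 1e-10)
})

test_that("session log-likelihood limits and sign", {
  tr <- ten_trial_fixture()
  m <- winning_model()
  # full lapse: every action has probability 1/2
  expect_equal(session_loglik(tr, winning_params(lapse = 1), m),
               10 * log(0.5), tolerance = 1e-12)
  expect_equal(session_loglik(tr[0, ], winning_params(), m), 0)
  set.seed(8)
  for (i in 1:20)
    expect_lte(session_loglik(tr, to_natural(m, rnorm(8)), m), 0)
  expect_equal(session_loglik(tr, NULL, random_responder()), 10 * log(0.5))
  expect_error(session_loglik(data.frame(stimulus = "XX", action = "go",
                                         reinforcement = 0L),
                              winning_params(), m),
               class = "avoidrl_parse_error")
})

test_that("nested variants tie exactly when extra parameters coincide", {
  sch <- build_session_schedule(task_design(), seed = 9)
  tr <- simulate_agent(sch, winning_model(), winning_params(), seed = 10)
  # 8-parameter model with approach == avoid equals 7-parameter shared-bias
  p8 <- winning_params(approach_bias = 1.2, avoidance_bias = 1.2)
  m7 <- gng_model("standard + 2 learning rates")
  p7 <- c(p8[c("reward_sensitivity", "punishment_sensitivity",
               "learning_rate_reward", "learning_rate_punishment", "lapse",
               "action_bias")], approach_avoid_bias = 1.2)
  expect_equal(session_loglik(tr, p8, winning_model()),
               session_loglik(tr, p7, m7), tolerance = 1e-12)
  # equal learning rates collapse to the shared-rate variants
  p8b <- winning_params(learning_rate_reward = 0.3,
                        learning_rate_punishment = 0.3)
  m5 <- gng_model("standard + 2 approach-avoid")
  p5 <- c(p8b[c("reward_sensitivity", "punishment_sensitivity")],
          learning_rate = 0.3,
          p8b[c("lapse", "action_bias", "approach_bias", "avoidance_bias")])
  expect_equal(session_loglik(tr, p8b, winning_model()),
               session_loglik(tr, p5, m5), tolerance = 1e-12)
  # equal sensitivities collapse to the single-sensitivity variant
  m6 <- gng_model("standard + 2 approach-avoid - 1 sense")
  p6 <- c(sensitivity = 3, learning_rate = 0.3,
          p8b[c("lapse", "action_bias", "approach_bias", "avoidance_bias")])
  expect_equal(session_loglik(tr, p5, m5), session_loglik(tr, p6, m6),
               tolerance = 1e-12)
})
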
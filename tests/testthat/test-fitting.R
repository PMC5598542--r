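test_that("finite-difference Hessian is exact on a quadratic", {
  A <- matrix(c(3, 1, 1, 2), 2, 2)
  f <- function(x) 0.5 * sum(x * (A %*% x))
  H <- avoidrl:::fd_hessian(f, c(0.3, -0.7), step = 1e-4)
  expect_equal(H, A, tolerance = 1e-5)
  # non-PD repair returns a positive-definite matrix
  B <- matrix(c(1, 0, 0, -2), 2, 2)
  Brep <- avoidrl:::nearest_pd(B)
  expect_true(all(eigen(Brep, symmetric = TRUE)$values > 0))
})

test_that("Laplace fit obeys the flat- and tight-prior limits (toy model)", {
  ll <- bernoulli_loglik(k = 30, n = 100)
  ml_logit <- stats::qlogis(0.3)
  starts <- matrix(c(0, -1, 1), ncol = 1)
  # flat prior: mode ~ maximum likelihood
  flat <- laplace_fit(ll, starts, prior_mean = 0, prior_var = 1e6)
  expect_equal(flat$mode, ml_logit, tolerance = 1e-3)
  # tight prior: mode ~ prior mean
  tight <- laplace_fit(ll, starts, prior_mean = 1.5, prior_var = 1e-6)
  expect_equal(tight$mode, 1.5, tolerance = 1e-2)
  # intermediate prior: shrinkage places the mode between ML and prior mean
  for (pm in c(-1, 0.5, 2)) {
    fit <- laplace_fit(ll, starts, prior_mean = pm, prior_var = 0.5)
    expect_true(fit$mode > min(ml_logit, pm) && fit$mode < max(ml_logit, pm))
  }
})

test_that("Laplace posterior moments match dense-grid quadrature", {
  ll <- bernoulli_loglik(k = 120, n = 200)
  fit <- laplace_fit(ll, matrix(c(0, 1), ncol = 1), prior_mean = 0,
                     prior_var = 1)
  grid <- grid_posterior_moments(ll, 0, 1)
  expect_equal(fit$mode, grid$mean, tolerance = 0.02)
  expect_equal(drop(fit$sigma), grid$var, tolerance = 0.05)
})

test_that("maximum-likelihood initialization: ceiling, restarts, consistency", {
  m <- winning_model()
  sch <- build_session_schedule(task_design(), seed = 1)
  # near-random data: fitted likelihood approaches the n log(1/2) ceiling
  tr <- simulate_agent(sch[sch$condition == "safe", ], m,
                       winning_params(lapse = 0.98), seed = 2)
  tr <- cbind(subject_id = "s", group = "control", tr,
              stringsAsFactors = FALSE)
  u <- split_units(tr)
  ml <- ml_initialize(u, m, quick_config(n_random_restarts = 3))
  expect_equal(ml$loglik[1] / (240 * log(0.5)), 1, tolerance = 0.02)
  expect_false(any(ml$failed))
  # more restarts can only improve the best likelihood (same seed)
  tr2 <- simulate_agent(sch[sch$condition == "safe", ], m, winning_params(),
                        seed = 3)
  tr2 <- cbind(subject_id = "s", group = "control", tr2,
               stringsAsFactors = FALSE)
  u2 <- split_units(tr2)
  ll1 <- ml_initialize(u2, m, quick_config(n_random_restarts = 1))$loglik
  ll5 <- ml_initialize(u2, m, quick_config(n_random_restarts = 5))$loglik
  expect_gte(ll5 + 1e-6, ll1)
})

test_that("maximum likelihood is consistent on a long synthetic session", {
  m <- winning_model()
  truth <- winning_params()
  d <- task_design(n_blocks = 50, trials_per_block = 200)  # 10,000 trials
  sch <- build_session_schedule(d, seed = 2)
  tr <- simulate_agent(sch, m, truth, seed = 3)
  tr <- cbind(subject_id = "s", group = "control", tr,
              stringsAsFactors = FALSE)
  tr$condition <- "safe"
  u <- split_units(tr)
  ml <- ml_initialize(u, m, quick_config(n_random_restarts = 3, seed = 4))
  est <- to_natural(m, ml$estimates[1, ])
  relerr <- abs(est - truth[m$params]) / truth[m$params]
  # sensitivities and Pavlovian biases are well identified; the learning
  # rates, lapse and the (0,1)-bounded action bias trade off against them
  # and carry wider sampling error even at this length
  tight <- c("reward_sensitivity", "punishment_sensitivity",
             "learning_rate_punishment", "approach_bias", "avoidance_bias")
  expect_true(all(relerr[tight] < 0.10))
  expect_true(all(relerr < 0.25))
})

test_that("E-step limits: flat prior gives ML, tight prior gives the mean", {
  m <- gng_model("standard")
  coh <- null_cohort(n_per_group = 1, seed = 5)
  units <- split_units(coh)[1]
  cfg <- quick_config()
  ml <- ml_initialize(units, m, cfg)
  flat <- e_step(units, list(mean = rep(0, 6), var = rep(1e5, 6)), m, cfg,
                 warm_starts = ml$estimates)
  expect_equal(unname(flat[[1]]$mode), unname(ml$estimates[1, ]),
               tolerance = 0.05)
  mu0 <- c(1, 1, 0, -1, 0.4, 0)
  tight <- e_step(units, list(mean = mu0, var = rep(1e-8, 6)), m, cfg)
  expect_equal(unname(tight[[1]]$mode), mu0, tolerance = 1e-3)
  expect_error(e_step(units, list(mean = rep(0, 6), var = rep(0, 6)), m, cfg),
               class = "avoidrl_spec_error")
})

test_that("M-step moments, floor and permutation invariance", {
  m <- gng_model("standard - action bias")  # 5 parameters
  mk_post <- function(mode, pvar) {
    list(mode = stats::setNames(mode, m$params),
         sigma = diag(pvar, m$np), failed = FALSE)
  }
  # identical modes, zero posterior variance -> variance at the floor
  pr <- m_step(list(mk_post(rep(1, 5), 0), mk_post(rep(1, 5), 0)), m,
               variance_floor = 1e-6)
  expect_equal(unname(pr$mean), rep(1, 5))
  expect_equal(unname(pr$var), rep(1e-6, 5))
  # modes at +/-1 with negligible posterior variance: mean 0, variance ~ 1
  pr2 <- m_step(list(mk_post(rep(1, 5), 1e-12), mk_post(rep(-1, 5), 1e-12)),
                m)
  expect_equal(unname(pr2$mean), rep(0, 5))
  expect_equal(unname(pr2$var), rep(1, 5), tolerance = 1e-9)
  # posterior uncertainty contributes to the population variance
  pr3 <- m_step(list(mk_post(rep(1, 5), 0.5), mk_post(rep(-1, 5), 0.5)), m)
  expect_equal(unname(pr3$var), rep(1.5, 5), tolerance = 1e-9)
  # order invariance
  posts <- list(mk_post(rnorm(5), 0.2), mk_post(rnorm(5), 0.1),
                mk_post(rnorm(5), 0.3))
  expect_equal(m_step(posts, m), m_step(rev(posts), m))
  expect_error(m_step(posts[1], m), class = "avoidrl_degenerate_error")
})

test_that("EM is deterministic, near-monotone, and contracts duplicate units", {
  m <- gng_model("standard")
  coh <- null_cohort(n_per_group = 3, seed = 7)
  units <- split_units(coh)
  cfg <- quick_config(max_iterations = 8)
  fit1 <- run_em(units, m, cfg)
  fit2 <- run_em(units, m, cfg)
  expect_identical(fit1$prior, fit2$prior)
  expect_identical(lapply(fit1$posteriors, `[[`, "mode"),
                   lapply(fit2$posteriors, `[[`, "mode"))
  # EM objective (summed Laplace evidence) is approximately monotone: any
  # per-step decrease stays a small fraction of the objective magnitude,
  # and the trace settles (Laplace-EM does not guarantee strict ascent)
  expect_true(all(diff(fit1$trace) > -0.005 * abs(fit1$trace[1])))
  expect_lt(abs(diff(utils::tail(fit1$trace, 2))), 0.5)
  # duplicated single unit: population variance decreases across EM toward
  # the posterior-variance level
  dup <- rep(units[1], 6)
  for (i in seq_along(dup)) dup[[i]]$id <- paste0("u", i)
  fit_dup <- run_em(dup, m, quick_config(max_iterations = 6))
  modes <- do.call(rbind, lapply(fit_dup$posteriors, `[[`, "mode"))
  # no between-unit spread: all modes coincide and the population variance
  # settles at the residual (Laplace posterior) level, well below 1
  expect_lt(max(apply(modes, 2, function(x) diff(range(x)))), 1e-4)
  pvar <- colMeans(do.call(rbind, lapply(fit_dup$posteriors,
                                         function(p) diag(p$sigma))))
  expect_equal(unname(fit_dup$prior$var), unname(pvar), tolerance = 0.2)
})

test_that("hierarchical shrinkage pulls unit modes toward the prior mean", {
  # one-parameter toy problems via the generic Laplace machinery
  set.seed(11)
  for (i in 1:20) {
    k <- rbinom(1, 60, runif(1, 0.2, 0.8))
    ll <- bernoulli_loglik(k, 60)
    pm <- rnorm(1)
    mlv <- stats::qlogis(max(min(k / 60, 0.99), 0.01))
    fit <- laplace_fit(ll, matrix(c(0, pm), ncol = 1), prior_mean = pm,
                       prior_var = 0.7)
    expect_true(fit$mode >= min(mlv, pm) - 1e-6 &&
                  fit$mode <= max(mlv, pm) + 1e-6)
  }
})
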
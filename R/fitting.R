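#' Configuration for the hierarchical EM fit
#'
#' @param max_iterations Maximum EM iterations (>= 1).
#' @param convergence_tolerance Convergence threshold on the change in the
#'   summed per-unit log-posterior between iterations.
#' @param n_random_restarts Number of optimization starts per unit per
#'   E-step (>= 1); the first start is warm (previous mode or maximum
#'   likelihood estimate), the rest are drawn from the current prior.
#' @param seed Integer seed controlling restart draws and Monte-Carlo
#'   evidence samples.
#' @param hessian_step Step size for the central-finite-difference Hessian
#'   at the posterior mode.
#' @param variance_floor Lower bound applied to population variances in the
#'   M-step, preventing prior collapse.
#' @param n_mc_samples Monte-Carlo samples per unit for the evidence
#'   integral used by [ibic()].
#' @return An `em_config` object.
#' @export
em_config <- function(max_iterations = 50L, convergence_tolerance = 1e-3,
                      n_random_restarts = 5L, seed = 1L,
                      hessian_step = 1e-4, variance_floor = 1e-6,
                      n_mc_samples = 2000L) {
  stopifnot(max_iterations >= 1L, n_random_restarts >= 1L,
            convergence_tolerance > 0, hessian_step > 0, variance_floor > 0,
            n_mc_samples >= 1L)
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tolerance = convergence_tolerance,
                 n_random_restarts = as.integer(n_random_restarts),
                 seed = as.integer(seed), hessian_step = hessian_step,
                 variance_floor = variance_floor,
                 n_mc_samples = as.integer(n_mc_samples)),
            class = "em_config")
}

#' Split a trial table into fitting units
#'
#' The fitting unit is a subject-condition session: every subject
#' contributes one safe and one threat unit, each fitted with its own
#' parameter vector.
#'
#' @param trials Trial table (see [read_trials()] for the schema).
#' @return List of units, each a list with `id`, `subject_id`, `group`,
#'   `condition` and `trials` (ordered by `trial_index`).
#' @export
split_units <- function(trials) {
  key <- interaction(trials$subject_id, trials$condition, drop = TRUE)
  lapply(split(trials, key), function(d) {
    d <- d[order(d$trial_index), , drop = FALSE]
    list(id = paste(d$subject_id[1], d$condition[1], sep = ":"),
         subject_id = d$subject_id[1], group = d$group[1],
         condition = d$condition[1], trials = d)
  })
}

# ---- generic Laplace machinery ---------------------------------------------

# Central-finite-difference Hessian of f at x.
fd_hessian <- function(f, x, step = 1e-4) {
  k <- length(x)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, step)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / step^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(k), j, step)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * step^2)
    }
  }
  (H + t(H)) / 2
}

# Repair a symmetric matrix to the nearest positive-definite one by
# flooring its eigenvalues.
nearest_pd <- function(H, eps = 1e-6) {
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors)
}

#' Laplace approximation of a posterior with a Gaussian prior
#'
#' Maximizes `loglik(x) + sum(dnorm(x, prior_mean, sqrt(prior_var), log))`
#' over unconstrained space from multiple starts and returns the mode, the
#' central-finite-difference Hessian of the negative log-posterior at the
#' mode (repaired to the nearest positive-definite matrix when necessary)
#' and the posterior covariance (its inverse).  With `prior_mean`/
#' `prior_var` set to `NULL` the unpenalized likelihood is maximized
#' instead and no Hessian is computed unless requested.
#'
#' @param loglik Function of one unconstrained parameter vector returning a
#'   scalar log-likelihood.
#' @param starts Matrix of starting points (one row per start).
#' @param prior_mean,prior_var Prior means and variances (or `NULL` for
#'   pure maximum likelihood).
#' @param hessian Compute the Hessian/covariance at the mode?
#' @param step Finite-difference step for the Hessian.
#' @param bounds Box half-width for the optimizer (unconstrained space).
#' @return List with `mode`, `value` (log-posterior or log-likelihood at
#'   the mode), and when `hessian = TRUE` also `hessian`, `sigma` and
#'   `repaired`.
#' @export
laplace_fit <- function(loglik, starts, prior_mean = NULL, prior_var = NULL,
                        hessian = TRUE, step = 1e-4, bounds = 12) {
  if (is.null(dim(starts))) starts <- matrix(starts, nrow = 1)
  k <- ncol(starts)
  if (k == 0L) {  # zero-parameter model: nothing to optimize
    v <- loglik(numeric(0))
    return(list(mode = numeric(0), value = v,
                hessian = matrix(0, 0, 0), sigma = matrix(0, 0, 0),
                repaired = FALSE))
  }
  neg <- function(x) {
    lp <- loglik(x)
    if (!is.null(prior_mean))
      lp <- lp + sum(stats::dnorm(x, prior_mean, sqrt(prior_var), log = TRUE))
    if (!is.finite(lp)) return(1e10)
    -lp
  }
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(starts[r, ], -bounds), bounds), neg,
                   method = "L-BFGS-B", lower = -bounds, upper = bounds,
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    return(list(mode = rep(NA_real_, k), value = NA_real_, failed = TRUE))
  out <- list(mode = best$par, value = -best$value, failed = FALSE)
  if (hessian) {
    H <- fd_hessian(neg, best$par, step = step)
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
    repaired <- any(ev <= 0)
    if (repaired) H <- nearest_pd(H)
    out$hessian <- H
    out$sigma <- tryCatch(solve(H), error = function(e) solve(nearest_pd(H)))
    out$repaired <- repaired
  }
  out
}

# ---- EM phases --------------------------------------------------------------

# Precomputed index map from a model's free parameters to the canonical
# full 8-slot natural parameter vector (absent slots point at a trailing 0).
theta_index_map <- function(spec) {
  p <- spec$params
  pick <- function(...) {
    hit <- match(c(...), p)
    hit <- hit[!is.na(hit)]
    if (length(hit)) hit[1] else length(p) + 1L  # trailing zero slot
  }
  c(pick("sensitivity", "reward_sensitivity"),
    pick("sensitivity", "punishment_sensitivity"),
    pick("learning_rate_reward", "learning_rate"),
    pick("learning_rate_punishment", "learning_rate"),
    pick("lapse"),
    pick("action_bias"),
    pick("approach_bias", "approach_avoid_bias"),
    pick("avoidance_bias", "approach_avoid_bias"))
}

# Log-likelihood closure for one unit in unconstrained space (hot path:
# avoids name matching on every evaluation).
unit_loglik_fn <- function(unit, spec) {
  enc <- encode_trials(unit$trials)
  if (isTRUE(spec$random)) {
    n <- length(enc$stimulus)
    return(function(x) n * log(0.5))
  }
  exp_i <- which(PARAM_TRANSFORMS[spec$params] == "exp")
  sig_i <- which(PARAM_TRANSFORMS[spec$params] == "sigmoid")
  idx8 <- theta_index_map(spec)
  has_ab <- spec$has_action_bias
  has_aa <- spec$has_approach_avoid
  function(x) {
    nat <- numeric(length(x) + 1L)
    nat[exp_i] <- exp(x[exp_i])
    nat[sig_i] <- 1 / (1 + exp(-x[sig_i]))
    gng_session_loglik_cpp(enc$stimulus, enc$action, enc$reinforcement,
                           nat[idx8], has_ab, has_aa)
  }
}

#' Per-unit maximum-likelihood initialization
#'
#' Unpenalized maximum of each unit's session log-likelihood over
#' unconstrained space, taken over `n_random_restarts` optimizer starts
#' (origin plus random draws).  Units on which every restart fails are
#' flagged, not dropped silently.
#'
#' @param units List from [split_units()].
#' @param spec A `gng_model`.
#' @param config An [em_config()].
#' @return List with `estimates` (units x parameters matrix, unconstrained
#'   space), `loglik` (vector) and `failed` (logical vector).
#' @export
ml_initialize <- function(units, spec, config = em_config()) {
  stopifnot(length(units) >= 1L)
  k <- spec$np
  with_seed(derive_seed(config$seed, "ml-init"), {
    est <- matrix(NA_real_, length(units), k,
                  dimnames = list(vapply(units, `[[`, "", "id"), spec$params))
    ll <- rep(NA_real_, length(units))
    failed <- logical(length(units))
    for (i in seq_along(units)) {
      fn <- unit_loglik_fn(units[[i]], spec)
      starts <- rbind(numeric(k),
                      matrix(stats::rnorm((config$n_random_restarts - 1) * k,
                                          0, 1.5),
                             ncol = k))
      fit <- laplace_fit(fn, starts, hessian = FALSE)
      if (isTRUE(fit$failed)) {
        failed[i] <- TRUE
        warning(sprintf("maximum-likelihood initialization failed for unit %s",
                        units[[i]]$id))
      } else {
        est[i, ] <- fit$mode
        ll[i] <- fit$value
      }
    }
    list(estimates = est, loglik = ll, failed = failed)
  })
}

#' E-step: Laplace posteriors for every unit under the current prior
#'
#' @param units List from [split_units()].
#' @param prior List with named vectors `mean` and `var` (unconstrained
#'   space, one entry per model parameter).
#' @param spec A `gng_model`.
#' @param config An [em_config()].
#' @param warm_starts Optional units x parameters matrix of starting points
#'   (previous modes or ML estimates).
#' @return List of unit posteriors: `unit_id`, `mode` (unconstrained),
#'   `mode_natural`, `hessian`, `sigma`, `log_posterior`,
#'   `laplace_evidence` (the unit's Laplace-approximate log marginal
#'   likelihood), `repaired`.
#' @export
e_step <- function(units, prior, spec, config = em_config(),
                   warm_starts = NULL) {
  check_prior(prior, spec)
  k <- spec$np
  with_seed(derive_seed(config$seed, "e-step"), {
    lapply(seq_along(units), function(i) {
      fn <- unit_loglik_fn(units[[i]], spec)
      warm <- if (!is.null(warm_starts) && all(is.finite(warm_starts[i, ])))
        warm_starts[i, ] else prior$mean
      starts <- rbind(warm,
                      if (config$n_random_restarts > 1)
                        matrix(stats::rnorm((config$n_random_restarts - 1) * k,
                                            rep(prior$mean,
                                                each = config$n_random_restarts - 1),
                                            rep(sqrt(prior$var),
                                                each = config$n_random_restarts - 1)),
                               ncol = k))
      fit <- laplace_fit(fn, starts, prior_mean = prior$mean,
                         prior_var = prior$var, hessian = TRUE,
                         step = config$hessian_step)
      mode <- stats::setNames(fit$mode, spec$params)
      # Laplace approximation to this unit's log marginal likelihood:
      # log p(data | prior) ~ logpost(mode) + k/2 log(2 pi) - 1/2 log|H|
      lev <- if (isTRUE(fit$failed)) NA_real_ else if (k == 0L) fit$value else
        fit$value + k / 2 * log(2 * pi) -
          0.5 * determinant(fit$hessian, logarithm = TRUE)$modulus[1]
      list(unit_id = units[[i]]$id, mode = mode,
           mode_natural = if (k > 0 && !isTRUE(fit$failed))
             to_natural(spec, mode) else mode,
           hessian = fit$hessian, sigma = fit$sigma,
           log_posterior = fit$value, laplace_evidence = lev,
           repaired = isTRUE(fit$repaired), failed = isTRUE(fit$failed))
    })
  })
}

check_prior <- function(prior, spec) {
  stopifnot(is.list(prior), length(prior$mean) == spec$np,
            length(prior$var) == spec$np)
  if (any(prior$var <= 0))
    stop_avoidrl("prior variances must be positive", "avoidrl_spec_error")
  invisible(prior)
}

#' M-step: update the population prior from unit posteriors
#'
#' Per parameter independently, the new mean is the average of the
#' posterior modes and the new variance is the average of
#' `mode^2 + Laplace posterior variance` minus the squared new mean,
#' floored at `variance_floor`.
#'
#' @param posteriors List from [e_step()].
#' @param spec A `gng_model`.
#' @param variance_floor Positive lower bound for the variances.
#' @return List with named vectors `mean` and `var`.
#' @export
m_step <- function(posteriors, spec, variance_floor = 1e-6) {
  posteriors <- Filter(function(p) !isTRUE(p$failed), posteriors)
  if (length(posteriors) < 2L)
    stop_avoidrl("m_step needs at least 2 units", "avoidrl_degenerate_error")
  modes <- do.call(rbind, lapply(posteriors, `[[`, "mode"))
  pvars <- do.call(rbind, lapply(posteriors, function(p) diag(p$sigma)))
  # Near-singular Hessians (unconverged modes, flat directions) can report
  # astronomically large Laplace variances; cap each unit's contribution at
  # a level that is already diffuse on the transformed scales (sd 5 spans
  # more than four orders of magnitude through exp).
  pvars <- pmin(pvars, 25)
  mu <- colMeans(modes)
  v <- pmax(pmin(colMeans(modes^2 + pvars) - mu^2, 25), variance_floor)
  list(mean = stats::setNames(mu, spec$params),
       var = stats::setNames(v, spec$params))
}

#' Hierarchical type-II maximum-likelihood EM over one prior group
#'
#' Alternates [e_step()] and [m_step()] from a prior derived from the
#' per-unit maximum-likelihood estimates until the EM objective -- the
#' summed per-unit Laplace-approximate log marginal likelihood -- changes
#' by less than the tolerance, or until the iteration cap is reached (in
#' which case the result carries `converged = FALSE`, never an error).
#'
#' @inheritParams e_step
#' @return A `gng_em_fit`: `model`, `prior`, `posteriors`, `trace`
#'   (EM objective per iteration), `converged`, `n_iterations`,
#'   `ml` (initialization result), `units_meta`, `config`.
#' @export
run_em <- function(units, spec, config = em_config()) {
  stopifnot(length(units) >= 2L)
  ml <- ml_initialize(units, spec, config)
  est <- ml$estimates
  prior <- if (spec$np > 0) {
    # Moments of the per-unit ML estimates, winsorized: unpenalized ML
    # routinely drives weakly identified parameters to the optimizer box,
    # and those runaway values would otherwise seed a wildly overdispersed
    # prior.  Bounds are loose on the natural scale (|x| = 5 covers
    # sensitivities up to ~150 and rates up to 0.99).
    est_cl <- pmin(pmax(est, -5), 5)
    mu <- colMeans(est_cl, na.rm = TRUE)
    v <- apply(est_cl, 2, stats::var, na.rm = TRUE)
    v[!is.finite(v)] <- 1
    v <- pmax(pmin(v, 2.25), 0.04)
    list(mean = mu, var = v)
  } else list(mean = numeric(0), var = numeric(0))
  trace <- numeric(0)
  warm <- est
  posteriors <- NULL
  converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    posteriors <- e_step(units, prior, spec, config, warm_starts = warm)
    # EM objective: summed per-unit Laplace log marginal likelihood (the
    # quantity type-II ML increases; posterior densities at the mode are
    # not comparable across different priors).
    obj <- sum(vapply(posteriors, `[[`, 0, "laplace_evidence"), na.rm = TRUE)
    trace <- c(trace, obj)
    if (it > 1 && abs(obj - trace[it - 1]) < config$convergence_tolerance) {
      converged <- TRUE
      break
    }
    if (spec$np > 0) {
      prior <- m_step(posteriors, spec, config$variance_floor)
      warm <- do.call(rbind, lapply(posteriors, `[[`, "mode"))
    } else if (it >= 2) {
      converged <- TRUE
      break
    }
  }
  structure(list(
    model = spec, prior = prior, posteriors = posteriors, trace = trace,
    converged = converged, n_iterations = length(trace), ml = ml,
    units_meta = data.frame(
      unit_id = vapply(units, `[[`, "", "id"),
      subject_id = vapply(units, `[[`, "", "subject_id"),
      group = vapply(units, `[[`, "", "group"),
      condition = vapply(units, `[[`, "", "condition"),
      n_trials = vapply(units, function(u) nrow(u$trials), 0L),
      stringsAsFactors = FALSE),
    config = config), class = "gng_em_fit")
}

#' @export
print.gng_em_fit <- function(x, ...) {
  cat(sprintf("<gng_em_fit> model '%s', %d units, %d EM iterations (%s)\n",
              x$model$name, nrow(x$units_meta), x$n_iterations,
              if (x$converged) "converged" else "iteration cap reached"))
  if (x$model$np > 0)
    print(round(rbind(mean = x$prior$mean, sd = sqrt(x$prior$var)), 3))
  invisible(x)
}

#' Recovered parameters of a fit as a tidy table
#'
#' @param fit A `gng_em_fit` (or one cell of a [fit_model()] result).
#' @param space "natural" or "unconstrained".
#' @return Data frame with unit metadata and one column per parameter.
#' @export
parameter_table <- function(fit, space = c("natural", "unconstrained")) {
  space <- match.arg(space)
  vals <- do.call(rbind, lapply(fit$posteriors, function(p)
    if (space == "natural") p$mode_natural else p$mode))
  cbind(fit$units_meta, as.data.frame(vals))
}
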
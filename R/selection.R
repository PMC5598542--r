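#' Population-prior partition schemes
#'
#' Four ways of grouping the subject-condition units under top-level prior
#' distributions: one prior per group-by-condition cell (`four_dist`), one
#' per condition blind to group (`two_dist_condition`), a single prior for
#' everyone (`one_dist`, each subject appearing twice, once per
#' condition), and one per group blind to condition (`two_dist_group`).
#'
#' @return Named list of `partition_scheme` objects, each with a `name` and
#'   an `assign(group, condition)` function returning the cell label.
#' @export
partition_schemes <- function() {
  mk <- function(name, assign) structure(list(name = name, assign = assign),
                                         class = "partition_scheme")
  list(
    four_dist = mk("four_dist", function(group, condition)
      paste(group, condition, sep = ".")),
    two_dist_condition = mk("two_dist_condition", function(group, condition)
      condition),
    one_dist = mk("one_dist", function(group, condition)
      rep("all", length(group))),
    two_dist_group = mk("two_dist_group", function(group, condition) group)
  )
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat(sprintf("<partition_scheme> %s\n", x$name))
  invisible(x)
}

get_scheme <- function(scheme) {
  if (inherits(scheme, "partition_scheme")) return(scheme)
  s <- partition_schemes()[[scheme]]
  if (is.null(s))
    stop_avoidrl(sprintf("unknown partition scheme '%s'", scheme),
                 "avoidrl_spec_error")
  s
}

# Partition a unit list into scheme cells (named list of unit lists).
split_units_by_scheme <- function(units, scheme) {
  scheme <- get_scheme(scheme)
  labels <- mapply(scheme$assign,
                   vapply(units, `[[`, "", "group"),
                   vapply(units, `[[`, "", "condition"))
  split(units, labels)
}

# ---- evidence ---------------------------------------------------------------

#' Monte-Carlo log evidence under a Gaussian prior
#'
#' Log of the Monte-Carlo average of `exp(loglik(x))` over draws of `x`
#' from the (diagonal) Gaussian prior, computed with log-sum-exp.
#'
#' @param loglik Function of one unconstrained parameter vector.
#' @param prior_mean,prior_var Prior means and variances.
#' @param n_samples Number of Monte-Carlo draws (>= 1).
#' @param seed Integer seed; the estimate is deterministic given the seed.
#' @return Scalar log evidence (`-Inf`, with a warning, if every draw has
#'   zero likelihood).
#' @export
mc_log_evidence <- function(loglik, prior_mean, prior_var, n_samples = 2000L,
                            seed = 1L) {
  k <- length(prior_mean)
  if (k == 0L) return(loglik(numeric(0)))  # no integral to take
  with_seed(derive_seed(seed, "evidence"), {
    draws <- matrix(stats::rnorm(n_samples * k, rep(prior_mean, each = n_samples),
                                 rep(sqrt(prior_var), each = n_samples)),
                    ncol = k)
    lls <- apply(draws, 1, loglik)
    out <- logsumexp(lls) - log(n_samples)
    if (!is.finite(out))
      warning("all Monte-Carlo likelihood draws were zero; evidence is -Inf")
    out
  })
}

#' Log evidence of one unit under a fitted population prior
#'
#' The integral of the unit's likelihood over the individual parameters,
#' approximated by prior Monte-Carlo (see [mc_log_evidence()]).  For the
#' zero-parameter random responder the integral collapses to the exact
#' value `n * log(0.5)`.
#'
#' @param unit One element of [split_units()].
#' @param prior List with `mean` and `var` (unconstrained space).
#' @param spec A `gng_model`.
#' @param n_mc_samples Monte-Carlo draws (>= 100 recommended).
#' @param seed Integer seed.
#' @return Scalar log evidence.
#' @export
unit_log_evidence <- function(unit, prior, spec, n_mc_samples = 2000L,
                              seed = 1L) {
  fn <- unit_loglik_fn(unit, spec)
  mc_log_evidence(fn, prior$mean, prior$var, n_samples = n_mc_samples,
                  seed = derive_seed(seed, unit$id))
}

#' Integrated BIC for one prior cell
#'
#' `-2 * sum(unit log evidence) + k * log(N)` where `k` counts the free
#' top-level quantities of the cell's prior (a mean and a variance per
#' model parameter, so `2 * np`) and `N` is the total number of trials
#' across the cell's units.  Smaller is better.
#'
#' @param units Non-empty list of units in the cell.
#' @param prior Fitted prior for the cell.
#' @param spec A `gng_model`.
#' @param n_mc_samples,seed Passed to [unit_log_evidence()].
#' @return Scalar iBIC.
#' @export
ibic <- function(units, prior, spec, n_mc_samples = 2000L, seed = 1L) {
  if (length(units) == 0L)
    stop_avoidrl("empty partition cell", "avoidrl_partition_error")
  ev <- vapply(units, unit_log_evidence, 0, prior = prior, spec = spec,
               n_mc_samples = n_mc_samples, seed = seed)
  n_total <- sum(vapply(units, function(u) nrow(u$trials), 0L))
  -2 * sum(ev) + 2 * spec$np * log(n_total)
}

# ---- fitting a model under a scheme ----------------------------------------

#' Fit one model under one partition scheme
#'
#' Runs [run_em()] independently in every cell of the scheme and scores
#' each cell by [ibic()] under its fitted prior.
#'
#' @param trials Trial table.
#' @param model A `gng_model` or variant name.
#' @param scheme A `partition_scheme` or scheme name.
#' @param config An [em_config()].
#' @return A `gng_fit`: `model`, `scheme`, `cells` (named list of
#'   `gng_em_fit`), `ibic_per_distribution`, `ibic_total`.
#' @export
fit_model <- function(trials, model = winning_model(), scheme = "one_dist",
                      config = em_config()) {
  if (is.character(model)) model <- gng_model(model)
  scheme <- get_scheme(scheme)
  units <- split_units(trials)
  cells <- split_units_by_scheme(units, scheme)
  fits <- lapply(cells, run_em, spec = model, config = config)
  ib <- vapply(names(fits), function(cl)
    ibic(cells[[cl]], fits[[cl]]$prior, model,
         n_mc_samples = config$n_mc_samples,
         seed = derive_seed(config$seed, cl)), 0)
  structure(list(model = model, scheme = scheme, cells = fits,
                 ibic_per_distribution = ib, ibic_total = sum(ib),
                 config = config), class = "gng_fit")
}

#' @export
print.gng_fit <- function(x, ...) {
  cat(sprintf("<gng_fit> model '%s', scheme %s: iBIC = %.1f\n",
              x$model$name, x$scheme$name, x$ibic_total))
  invisible(x)
}

#' Pooled parameter table across the cells of a fit
#' @param fit A `gng_fit` from [fit_model()].
#' @inheritParams parameter_table
#' @return Data frame with one row per unit.
#' @export
fit_parameter_table <- function(fit, space = c("natural", "unconstrained")) {
  space <- match.arg(space)
  out <- do.call(rbind, lapply(fit$cells, parameter_table, space = space))
  rownames(out) <- NULL
  out
}

#' Compare all models and partition schemes by integrated BIC
#'
#' Fits every (model, scheme) combination with [fit_model()] and ranks the
#' combinations by total iBIC; the winner is the minimum.  Approximate
#' Bayes factors against the winner are `exp(delta_ibic / 2)`.  A
#' combination whose fit fails is kept in the table, flagged, and excluded
#' from winner selection.
#'
#' @param trials Trial table.
#' @param models List of `gng_model`s (default: all seven variants).
#' @param schemes List of schemes (default: all four).
#' @param config An [em_config()].
#' @return A `gng_comparison`: `table` (data frame sorted by iBIC with
#'   columns `model`, `scheme`, `ibic_total`, `delta_ibic`,
#'   `approx_bayes_factor`, `failed`), `winner` (list with `model`,
#'   `scheme`), and `fits` (named list of `gng_fit`).
#' @export
compare_models <- function(trials, models = list_model_specs(),
                           schemes = partition_schemes(),
                           config = em_config()) {
  models <- lapply(models, function(m) if (is.character(m)) gng_model(m) else m)
  schemes <- lapply(schemes, get_scheme)
  fits <- list()
  rows <- list()
  for (m in models) for (s in schemes) {
    key <- paste(m$name, s$name, sep = " | ")
    fit <- tryCatch(fit_model(trials, m, s, config), error = function(e) e)
    failed <- inherits(fit, "error")
    if (!failed) fits[[key]] <- fit
    rows[[key]] <- data.frame(
      model = m$name, scheme = s$name,
      ibic_total = if (failed) NA_real_ else fit$ibic_total,
      failed = failed, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- !tab$failed & is.finite(tab$ibic_total)
  if (!any(ok))
    stop_avoidrl("every model/scheme combination failed to fit",
                 "avoidrl_fit_error")
  best <- min(tab$ibic_total[ok])
  tab$delta_ibic <- tab$ibic_total - best
  tab$approx_bayes_factor <- exp(tab$delta_ibic / 2)
  tab <- tab[order(tab$ibic_total), ]
  rownames(tab) <- NULL
  win <- tab[1, ]
  structure(list(table = tab,
                 winner = list(model = win$model, scheme = win$scheme,
                               key = paste(win$model, win$scheme,
                                           sep = " | ")),
                 fits = fits, config = config), class = "gng_comparison")
}

#' @export
print.gng_comparison <- function(x, ...) {
  cat("<gng_comparison> winner:", x$winner$model, "/", x$winner$scheme, "\n")
  print(x$table[, c("model", "scheme", "ibic_total", "delta_ibic",
                    "approx_bayes_factor")], digits = 6)
  invisible(x)
}
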
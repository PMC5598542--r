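#' Two-tailed permutation tests on recovered parameters
#'
#' Distribution-free inference for group and condition effects on fitted
#' model parameters.  All tests are two-tailed on the mean difference.
#' When the number of distinct relabelings (or sign patterns) is no larger
#' than `n_permutations` the null distribution is enumerated exhaustively
#' and the p value is exact; otherwise it is estimated by Monte-Carlo
#' relabeling with the add-one rule
#' `p = (1 + #(|null| >= |observed|)) / (1 + n_permutations)`, so p is
#' never exactly zero.
#'
#' @param values_a,values_b Non-empty numeric vectors (independent groups).
#' @param n_permutations Permutation budget.
#' @param seed Integer seed (Monte-Carlo mode).
#' @return A `permutation_result` with `statistic_observed`,
#'   `null_statistics`, `p_two_tailed`, `n_permutations`, `exhaustive`,
#'   `test_kind`, `seed`.
#' @name permutation_tests
NULL

new_perm_result <- function(observed, null_stats, exhaustive, kind, seed,
                            n_permutations) {
  p <- if (length(null_stats) == 0L) {
    1
  } else if (exhaustive) {
    mean(abs(null_stats) >= abs(observed) - 1e-12)
  } else {
    (1 + sum(abs(null_stats) >= abs(observed) - 1e-12)) /
      (1 + length(null_stats))
  }
  structure(list(statistic_observed = observed, null_statistics = null_stats,
                 p_two_tailed = p, n_permutations = length(null_stats),
                 exhaustive = exhaustive, test_kind = kind, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s: statistic = %.4g, p = %.4g (%s, %d permutations)\n",
              x$test_kind, x$statistic_observed, x$p_two_tailed,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_permutations))
  invisible(x)
}

#' @rdname permutation_tests
#' @export
permutation_test_between <- function(values_a, values_b,
                                     n_permutations = 10000L, seed = 1L) {
  stopifnot(length(values_a) >= 1L, length(values_b) >= 1L)
  pooled <- c(values_a, values_b)
  na <- length(values_a)
  n <- length(pooled)
  observed <- mean(values_a) - mean(values_b)
  if (max(pooled) - min(pooled) == 0) {
    warning("all pooled values identical; p = 1 by convention")
    return(new_perm_result(0, numeric(0), TRUE, "between_group", seed, 0L))
  }
  n_exact <- choose(n, na)
  stat <- function(idx_a) mean(pooled[idx_a]) - mean(pooled[-idx_a])
  if (n_exact <= n_permutations) {
    combos <- utils::combn(n, na)
    null_stats <- apply(combos, 2, stat)
    new_perm_result(observed, null_stats, TRUE, "between_group", seed,
                    n_exact)
  } else {
    null_stats <- with_seed(derive_seed(seed, "perm-between"),
      vapply(seq_len(n_permutations),
             function(i) stat(sample.int(n, na)), 0))
    new_perm_result(observed, null_stats, FALSE, "between_group", seed,
                    n_permutations)
  }
}

#' @rdname permutation_tests
#' @param threat_minus_safe_a,threat_minus_safe_b Per-subject difference
#'   scores (threat minus safe) for the two groups; the interaction test
#'   is a between-group permutation test on these difference scores.
#' @export
interaction_test <- function(threat_minus_safe_a, threat_minus_safe_b,
                             n_permutations = 10000L, seed = 1L) {
  res <- permutation_test_between(threat_minus_safe_a, threat_minus_safe_b,
                                  n_permutations = n_permutations,
                                  seed = seed)
  res$test_kind <- "interaction_diff_scores"
  res
}

#' @rdname permutation_tests
#' @param paired_safe,paired_threat Equal-length paired vectors (same
#'   subject order); the within-group condition test sign-flips the
#'   per-subject differences.
#' @export
within_condition_test <- function(paired_safe, paired_threat,
                                  n_permutations = 10000L, seed = 1L) {
  if (length(paired_safe) != length(paired_threat))
    stop_avoidrl(sprintf("paired lists differ in length (%d vs %d)",
                         length(paired_safe), length(paired_threat)),
                 "avoidrl_pairing_error")
  d <- paired_threat - paired_safe
  n <- length(d)
  observed <- mean(d)
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1 by convention")
    return(new_perm_result(0, numeric(0), TRUE, "within_paired_signflip",
                           seed, 0L))
  }
  if (2^n <= n_permutations) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null_stats <- as.numeric(signs %*% d) / n
    new_perm_result(observed, null_stats, TRUE, "within_paired_signflip",
                    seed, 2^n)
  } else {
    null_stats <- with_seed(derive_seed(seed, "perm-within"), {
      signs <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                      ncol = n)
      as.numeric(signs %*% d) / n
    })
    new_perm_result(observed, null_stats, FALSE, "within_paired_signflip",
                    seed, n_permutations)
  }
}

#' Group and condition effects on one recovered parameter
#'
#' Runs the full permutation battery on one natural-space parameter of a
#' fitted model: the group main effect (subject means across conditions),
#' the group-by-condition interaction (between-group test on
#' threat-minus-safe difference scores), the group effect within each
#' condition, and the condition effect within each group (paired
#' sign-flip).
#'
#' @param fit A `gng_fit` or `gng_em_fit` covering both groups and
#'   conditions.
#' @param parameter Parameter name (natural space), e.g.
#'   `"avoidance_bias"`.
#' @param n_permutations,seed Passed to the individual tests.
#' @return Named list of `permutation_result` objects: `group_main`,
#'   `interaction`, `group_within_safe`, `group_within_threat`,
#'   `condition_within_control`, `condition_within_anx`.
#' @export
parameter_group_tests <- function(fit, parameter = "avoidance_bias",
                                  n_permutations = 10000L, seed = 1L) {
  pt <- if (inherits(fit, "gng_fit")) fit_parameter_table(fit)
        else parameter_table(fit)
  if (!parameter %in% names(pt))
    stop_avoidrl(sprintf("parameter '%s' not in fitted model", parameter),
                 "avoidrl_spec_error")
  wide <- stats::reshape(
    pt[, c("subject_id", "group", "condition", parameter)],
    direction = "wide", idvar = c("subject_id", "group"),
    timevar = "condition")
  vs <- paste0(parameter, ".safe")
  vt <- paste0(parameter, ".threat")
  if (anyNA(wide[, c(vs, vt)]))
    stop_avoidrl(paste("unmatched safe/threat pairs for subject(s):",
                       paste(wide$subject_id[!stats::complete.cases(
                         wide[, c(vs, vt)])], collapse = ", ")),
                 "avoidrl_pairing_error")
  hc <- wide$group == "control"
  subj_mean <- (wide[[vs]] + wide[[vt]]) / 2
  diffs <- wide[[vt]] - wide[[vs]]
  list(
    group_main = permutation_test_between(
      subj_mean[!hc], subj_mean[hc], n_permutations, derive_seed(seed, "gm")),
    interaction = interaction_test(
      diffs[!hc], diffs[hc], n_permutations, derive_seed(seed, "ix")),
    group_within_safe = permutation_test_between(
      wide[[vs]][!hc], wide[[vs]][hc], n_permutations,
      derive_seed(seed, "gs")),
    group_within_threat = permutation_test_between(
      wide[[vt]][!hc], wide[[vt]][hc], n_permutations,
      derive_seed(seed, "gt")),
    condition_within_control = within_condition_test(
      wide[[vs]][hc], wide[[vt]][hc], n_permutations,
      derive_seed(seed, "cc")),
    condition_within_anx = within_condition_test(
      wide[[vs]][!hc], wide[[vt]][!hc], n_permutations,
      derive_seed(seed, "ca")))
}
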
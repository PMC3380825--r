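#' Per-sign detection error rates of a GI screen
#'
#' Sensitivity is the fraction of true interactions a screen detects;
#' precision is the fraction of reported interactions that are true.
#' [costanzo_rates()] returns the published per-sign estimates for the
#' reference colony-growth screen, applied to all datasets because no
#' dataset-specific estimates exist.
#'
#' @param sensitivity,precision fractions in (0, 1].
#' @return an `error_rates` list.
#' @export
error_rates <- function(sensitivity, precision) {
  stopifnot(sensitivity > 0, sensitivity <= 1, precision > 0, precision <= 1)
  structure(list(sensitivity = sensitivity, precision = precision),
            class = "error_rates")
}

#' @rdname error_rates
#' @export
costanzo_rates <- function() {
  list(positive = error_rates(sensitivity = 0.18, precision = 0.59),
       negative = error_rates(sensitivity = 0.35, precision = 0.63))
}

#' Estimate the number of true interactions behind an observed count
#'
#' Of `n_obs` reported interactions, `n_obs * precision` are true
#' positives, which are a `sensitivity` fraction of all true interactions;
#' hence `T = n_obs * precision / sensitivity` — the unique inversion
#' consistent with the two rates.
#'
#' @param n_obs observed interaction count (>= 0).
#' @param rates an [error_rates()] object.
#' @return estimated true interaction count (real).
#' @export
estimate_truth_size <- function(n_obs, rates) {
  stopifnot(inherits(rates, "error_rates"), n_obs >= 0)
  n_obs * rates$precision / rates$sensitivity
}

#' Expected interaction sharing between two screens of one truth
#'
#' Generative model: the two datasets report from a single shared set of
#' `T` true interactions among `N` commonly tested pairs; each dataset
#' detects each true interaction independently (effective sensitivity
#' `s_X = n_X p / T`) and falsely calls each null pair independently
#' (false-positive rate `f_X = n_X (1 - p) / (N - T)`). `T` is the mean of
#' the two per-dataset inversions. Expected counts of pairs called in
#' both, only one, or neither dataset follow, as do the expected Jaccard
#' overlap and unique fractions (ratios of expectations).
#'
#' @param N number of commonly tested pairs.
#' @param n_a,n_b observed interaction counts (one sign class) in each
#'   dataset.
#' @param rates an [error_rates()] object for that sign class.
#' @return an `expected_counts` list with `N`, `T`, `s_a`, `s_b`, `f_a`,
#'   `f_b`, `E_both`, `E_only_a`, `E_only_b`, `E_neither`,
#'   `expected_overlap`, `expected_unique`.
#' @export
expected_counts <- function(N, n_a, n_b, rates) {
  stopifnot(inherits(rates, "error_rates"), n_a <= N, n_b <= N,
            n_a >= 0, n_b >= 0, N > 0)
  T_est <- mean(c(estimate_truth_size(n_a, rates),
                  estimate_truth_size(n_b, rates)))
  if (T_est >= N)
    stop("estimated truth size T = ", signif(T_est, 6), " >= N = ", N,
         ": precision/sensitivity inconsistent with these counts")
  p <- rates$precision
  s_a <- if (T_est > 0) n_a * p / T_est else 0
  s_b <- if (T_est > 0) n_b * p / T_est else 0
  s_a <- min(s_a, 1); s_b <- min(s_b, 1)
  f_a <- n_a * (1 - p) / (N - T_est)
  f_b <- n_b * (1 - p) / (N - T_est)
  E_both <- T_est * s_a * s_b + (N - T_est) * f_a * f_b
  E_only_a <- T_est * s_a * (1 - s_b) + (N - T_est) * f_a * (1 - f_b)
  E_only_b <- T_est * s_b * (1 - s_a) + (N - T_est) * f_b * (1 - f_a)
  E_neither <- N - E_both - E_only_a - E_only_b
  union_exp <- E_both + E_only_a + E_only_b
  structure(list(N = N, T = T_est, s_a = s_a, s_b = s_b, f_a = f_a,
                 f_b = f_b, E_both = E_both, E_only_a = E_only_a,
                 E_only_b = E_only_b, E_neither = E_neither,
                 expected_overlap = if (union_exp > 0) E_both / union_exp
                                    else NA_real_,
                 expected_unique = if (union_exp > 0)
                                     1 - E_both / union_exp else NA_real_),
            class = "expected_counts")
}

#' Monte-Carlo oracle for the expected-overlap model
#'
#' Simulates the generative process of [expected_counts()] directly:
#' each replicate draws, for the `T` (rounded) true pairs, independent
#' detection in each dataset with probabilities `s_a`, `s_b`, and for the
#' `N - T` null pairs independent false calls with rates `f_a`, `f_b`.
#' Returns empirical mean counts with standard errors of the mean.
#'
#' @inheritParams expected_counts
#' @param reps number of replicates (>= 1).
#' @param seed RNG seed.
#' @return list with `E_both`, `E_only_a`, `E_only_b`, `E_neither`,
#'   `expected_overlap` (means), matching `se_*` standard errors, and
#'   `reps`.
#' @export
monte_carlo_expected <- function(N, n_a, n_b, rates, reps = 2000,
                                 seed = 1L) {
  stopifnot(reps >= 1)
  ana <- expected_counts(N, n_a, n_b, rates)
  T_int <- as.integer(round(ana$T))
  null_int <- as.integer(N - T_int)
  p_true <- c(ana$s_a * ana$s_b, ana$s_a * (1 - ana$s_b),
              (1 - ana$s_a) * ana$s_b, (1 - ana$s_a) * (1 - ana$s_b))
  p_null <- c(ana$f_a * ana$f_b, ana$f_a * (1 - ana$f_b),
              (1 - ana$f_a) * ana$f_b, (1 - ana$f_a) * (1 - ana$f_b))
  with_seed(seed, {
    true_draw <- if (T_int > 0) stats::rmultinom(reps, T_int, p_true)
                 else matrix(0, 4, reps)
    null_draw <- if (null_int > 0) stats::rmultinom(reps, null_int, p_null)
                 else matrix(0, 4, reps)
    counts <- true_draw + null_draw  # rows: both, only_a, only_b, neither
    both <- counts[1, ]; only_a <- counts[2, ]; only_b <- counts[3, ]
    neither <- counts[4, ]
    un <- both + only_a + only_b
    ov <- ifelse(un > 0, both / un, NA_real_)
    sem <- function(v) stats::sd(v) / sqrt(length(v))
    list(E_both = mean(both), E_only_a = mean(only_a),
         E_only_b = mean(only_b), E_neither = mean(neither),
         expected_overlap = mean(ov, na.rm = TRUE),
         se_both = sem(both), se_only_a = sem(only_a),
         se_only_b = sem(only_b), se_neither = sem(neither),
         se_overlap = sem(ov[!is.na(ov)]), reps = reps)
  })
}

#' Observed/expected overlap and uniqueness ratios
#'
#' A ratio of 1 means the two datasets share exactly as many interactions
#' as their error rates predict for two error-prone observations of the
#' same truth; below 1 they share less than expected (genuinely divergent
#' biology), above 1 more (e.g. shared laboratory artifacts). Both
#' orientations are reported because the literature uses both.
#'
#' @param measures one row (one sign filter) of [compare_networks()]
#'   output, or any list with `overlap` and `unique` fields.
#' @param expected an [expected_counts()] object.
#' @return list with `ratio_overlap`, `ratio_unique` (observed/expected)
#'   and `ratio_overlap_inv`, `ratio_unique_inv` (expected/observed).
#' @export
overlap_ratio <- function(measures, expected) {
  obs_ov <- measures$overlap
  obs_un <- measures$unique
  exp_ov <- expected$expected_overlap
  exp_un <- expected$expected_unique
  rat <- function(o, e) {
    if (is.na(o) || is.na(e) || e == 0) NA_real_ else o / e
  }
  list(ratio_overlap = rat(obs_ov, exp_ov),
       ratio_unique = rat(obs_un, exp_un),
       ratio_overlap_inv = rat(exp_ov, obs_ov),
       ratio_unique_inv = rat(exp_un, obs_un))
}
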
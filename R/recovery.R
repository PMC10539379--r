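#' Replicate odds-ratio recovery at fixed group sizes
#'
#' Validation simulation for the logistic arm of the battery: per replicate,
#' a standardized score is drawn N(0, 1) for the pooled sample, case status is
#' assigned from a logistic model whose per-SD coefficient is
#' `log(or_per_sd)` and whose intercept is solved numerically so the expected
#' case count matches `n_cases`, and the per-SD OR is re-estimated with
#' [fit_logistic()].
#'
#' @param n_cases,n_controls target group sizes (defaults 1487 / 1483, the
#'   narrow_1 comparison).
#' @param or_per_sd generating odds ratio per SD of score.
#' @param n_reps number of replicates (default 500).
#' @param seed integer seed.
#' @return data.frame with one row per replicate: `or`, `beta`, `p`.
#' @export
recovery_or <- function(n_cases = 1487, n_controls = 1483, or_per_sd = 1.12,
                        n_reps = 500, seed = 1) {
  set.seed(seed)
  n <- n_cases + n_controls
  target <- n_cases / n
  b <- log(or_per_sd)
  out <- vapply(seq_len(n_reps), function(r) {
    z <- stats::rnorm(n)
    a <- stats::uniroot(function(a0)
      mean(stats::plogis(a0 + b * z)) - target,
      lower = -10, upper = 10, tol = 1e-10)$root
    status <- stats::rbinom(n, 1L, stats::plogis(a + b * z))
    fit <- fit_logistic(status, z)
    c(fit$or, fit$beta, fit$p)
  }, numeric(3))
  data.frame(or = out[1, ], beta = out[2, ], p = out[3, ])
}

#' Replicate mean-difference recovery at fixed group sizes
#'
#' Validation simulation for the t-test arm: per replicate, case scores are
#' drawn N(`shift`, 1) and control scores N(0, 1) at the given group sizes,
#' and the mean difference is re-estimated with [mean_difference_test()].
#'
#' @param n_cases,n_controls group sizes (defaults 1487 / 1483).
#' @param shift true standardized mean difference.
#' @param n_reps number of replicates (default 500).
#' @param seed integer seed.
#' @return data.frame with one row per replicate: `estimate`, `p`.
#' @export
recovery_mean_diff <- function(n_cases = 1487, n_controls = 1483,
                               shift = 0.107, n_reps = 500, seed = 1) {
  set.seed(seed)
  out <- vapply(seq_len(n_reps), function(r) {
    res <- mean_difference_test(stats::rnorm(n_cases, shift),
                                stats::rnorm(n_controls))
    c(res$estimate, res$p)
  }, numeric(2))
  data.frame(estimate = out[1, ], p = out[2, ])
}
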
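#' Mean-difference test between case and control scores
#'
#' Two-sided t-test of the standardized-score mean difference (cases minus
#' controls). Welch's unequal-variance form is the default; the pooled-variance
#' Student form is available for comparison.
#'
#' @param scores_cases,scores_controls numeric vectors, each of length >= 2.
#' @param var_equal use the pooled-variance form? Default FALSE (Welch).
#' @return list with `estimate` (mean difference), `t`, `df`, `p`, `conf_int`.
#' @export
mean_difference_test <- function(scores_cases, scores_controls,
                                 var_equal = FALSE) {
  stopifnot(length(scores_cases) >= 2, length(scores_controls) >= 2)
  if (stats::sd(scores_cases) == 0 && stats::sd(scores_controls) == 0)
    stop("zero variance in both groups")
  tt <- stats::t.test(scores_cases, scores_controls, var.equal = var_equal)
  list(estimate = unname(tt$estimate[1] - tt$estimate[2]),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, conf_int = unname(tt$conf.int))
}

#' Logistic regression of case status on a polygenic score
#'
#' Maximum-likelihood logistic fit of case/control status on a standardized
#' score plus optional covariates (typically the first four principal
#' components). Reports the odds ratio per SD of the score with a Wald 95%
#' confidence interval and two-sided Wald p-value, plus the log-likelihoods of
#' the full and covariate-only models (for Nagelkerke R-squared). Perfect
#' separation and rank-deficient designs are errors, not silent results.
#'
#' @param status 0/1 or logical outcome with both classes present.
#' @param score numeric predictor of interest.
#' @param covariates optional numeric matrix/data.frame of extra columns.
#' @param ci `"wald"` (default) or `"profile"` for the score CI.
#' @param level confidence level (default 0.95).
#' @return list with `or`, `beta`, `se`, `ci_lower`, `ci_upper`, `p`,
#'   `loglik_full`, `loglik_base`, `n`, `n_cases`, `fit` (the `glm`).
#' @export
fit_logistic <- function(status, score, covariates = NULL,
                         ci = c("wald", "profile"), level = 0.95) {
  ci <- match.arg(ci)
  status <- as.integer(as.logical(status))
  n <- length(status)
  stopifnot(length(score) == n)
  if (length(unique(status)) < 2L)
    stop("status must contain both cases and controls")
  X <- cbind(score = score)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    bad <- setdiff(seq_len(ncol(X) + 1L), qrX$pivot[seq_len(qrX$rank)])
    stop("rank-deficient design; collinear columns: ",
         paste(c("(Intercept)", colnames(X))[bad], collapse = ", "))
  }
  dat <- data.frame(status = status, X, check.names = FALSE)
  # the 0/1-fitted-probability warning is superseded by the explicit
  # separation check below
  fit <- withCallingHandlers(
    stats::glm(status ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  mu <- fit$fitted.values
  if (all(pmin(mu, 1 - mu) < 1e-6)) {
    # every fitted probability numerically 0/1: complete separation
    std_beta <- abs(stats::coef(fit)[-1]) * apply(X, 2, stats::sd)
    stop("(quasi-)perfect separation detected along '",
         names(which.max(std_beta)), "'")
  }
  sm <- summary(fit)$coefficients
  beta <- sm["score", "Estimate"]
  se <- sm["score", "Std. Error"]
  p <- sm["score", "Pr(>|z|)"]
  zq <- stats::qnorm(1 - (1 - level) / 2)
  if (ci == "wald") {
    lo <- beta - zq * se; hi <- beta + zq * se
  } else {
    cib <- suppressMessages(suppressWarnings(
      stats::confint(fit, parm = "score", level = level)))
    lo <- cib[1]; hi <- cib[2]
  }
  base <- if (is.null(covariates)) {
    stats::glm(status ~ 1, family = stats::binomial())
  } else {
    stats::glm(status ~ ., data = data.frame(status = status, covariates,
                                             check.names = FALSE),
               family = stats::binomial())
  }
  list(or = exp(beta), beta = beta, se = se,
       ci_lower = exp(lo), ci_upper = exp(hi), p = p,
       loglik_full = as.numeric(stats::logLik(fit)),
       loglik_base = as.numeric(stats::logLik(base)),
       n = n, n_cases = sum(status), fit = fit)
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell R-squared 1 - exp(2 (llbase - llfull) / n), rescaled by its
#' attainable maximum 1 - exp(2 llbase / n). Comparing the full model (score +
#' covariates) with the covariate-only baseline isolates the variance
#' attributable to the score.
#'
#' @param loglik_full,loglik_base model log-likelihoods, full >= base.
#' @param n sample size.
#' @return R-squared in \[0, 1\].
#' @export
nagelkerke_r2 <- function(loglik_full, loglik_base, n) {
  if (n <= 0) stop("n must be positive")
  if (loglik_full < loglik_base - 1e-8)
    stop("full-model log-likelihood below baseline")
  cs <- 1 - exp(2 * (loglik_base - loglik_full) / n)
  cs_max <- 1 - exp(2 * loglik_base / n)
  if (cs_max <= 0) return(0)
  min(max(cs / cs_max, 0), 1)
}

#' Convert observed-scale R-squared to the liability scale
#'
#' Threshold-model transformation for case-control data:
#' R2_liab = R2_obs * K^2 (1-K)^2 / (z^2 P (1-P)), where K is the population
#' proportion of cases, P the sample case proportion, and z the standard
#' normal density at the liability threshold qnorm(1 - K). The map is linear
#' in the observed R-squared.
#'
#' @param r2_observed observed-scale R-squared in \[0, 1\].
#' @param K population case proportion (default 0.10: the working assumption
#'   that one in ten MDD cases meets the stringent TRD definition).
#' @param P sample case proportion.
#' @return liability-scale R-squared.
#' @export
liability_r2 <- function(r2_observed, K = 0.10, P) {
  stopifnot(K > 0, K < 1, P > 0, P < 1,
            r2_observed >= 0, r2_observed <= 1)
  thr <- stats::qnorm(1 - K)
  z <- stats::dnorm(thr)
  r2_observed * (K * (1 - K))^2 / (z^2 * P * (1 - P))
}

#' Quartile trend test of case proportion against score quartile
#'
#' Splits subjects into quartiles of the pooled score distribution (Q1 lowest;
#' boundary ties fall to the lower quartile) and tests for a linear trend in
#' the case proportion across quartiles with the Cochran-Armitage test at
#' equally spaced scores 1-4 (one-degree-of-freedom chi-squared).
#'
#' @param scores numeric vector (pooled cases + controls), length >= 8.
#' @param status 0/1 or logical case indicator aligned to `scores`.
#' @return list with `table` (per-quartile cases, controls, case proportion),
#'   `statistic`, `p`.
#' @export
quartile_trend <- function(scores, status) {
  status <- as.integer(as.logical(status))
  n <- length(scores)
  stopifnot(n >= 8, length(status) == n)
  qs <- stats::quantile(scores, probs = c(0.25, 0.5, 0.75), type = 7)
  quart <- findInterval(scores, qs, left.open = TRUE) + 1L
  counts <- table(factor(quart, levels = 1:4), factor(status, levels = 0:1))
  if (any(rowSums(counts) == 0))
    stop("a score quartile contains no subjects")
  cases <- counts[, "1"]; tot <- rowSums(counts)
  tr <- suppressWarnings(stats::prop.trend.test(cases, tot, score = 1:4))
  list(table = data.frame(quartile = paste0("Q", 1:4),
                          n_cases = as.integer(cases),
                          n_controls = as.integer(counts[, "0"]),
                          case_proportion = as.numeric(cases / tot)),
       statistic = unname(tr$statistic), p = tr$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: with m tests sorted ascending, adjusted(i) =
#' min over j >= i of (m/j) p(j), capped at 1, returned in input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.631, 0.794, 0.742, 0.003, 0.004, 0.009))
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}
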
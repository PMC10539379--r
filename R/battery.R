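#' Fit the full TRD vs non-TRD association battery
#'
#' The central fitting function: for each TRD definition (broad, narrow_1,
#' narrow_2) and each treatment-response score (lithium response,
#' antidepressant response) it runs the mean-difference t-test and the
#' PC-adjusted logistic regression of TRD status on the standardized score,
#' computes Nagelkerke R-squared (full vs covariate-only model) and its
#' liability-scale conversion at population proportion `K`, and the quartile
#' trend test. Benjamini-Hochberg FDR is applied separately to the six
#' mean-difference p-values and the six regression p-values (exactly the six
#' primary tests enter each adjustment). Sensitivity refits add the
#' psychiatric-disorder scores (MDD, bipolar, both) as covariates and, for the
#' lithium score, drop lithium-using TRD cases.
#'
#' @param classifications data.frame from [classify_subjects()].
#' @param scores named list of [prs_score()] results (or any data.frame with
#'   `subject_id` and `z`); must contain the entries named by `traits`, and
#'   may contain `mdd` / `bip` for the covariate sensitivity refits.
#' @param pcs data.frame with `subject_id` and principal-component columns
#'   (the first `n_pcs` are used), computed within the analysis sample after
#'   QC; NULL fits unadjusted models.
#' @param traits character vector of the two primary score names
#'   (default `c("lithium", "antidep")`).
#' @param n_pcs number of PCs used as covariates (default 4).
#' @param K assumed population proportion of TRD among MDD (default 0.10).
#' @param var_equal pooled-variance t-test instead of Welch? Default FALSE.
#' @param sensitivity run the covariate and lithium-exclusion refits? Default
#'   TRUE.
#' @return object of class `trd_battery`: list with `primary` (one row per
#'   definition x trait), `sensitivity`, `quartiles`, and the parameters used.
#' @export
run_battery <- function(classifications, scores, pcs = NULL,
                        traits = c("lithium", "antidep"), n_pcs = 4,
                        K = 0.10, var_equal = FALSE, sensitivity = TRUE) {
  stopifnot(all(traits %in% names(scores)))
  definitions <- c("broad", "narrow_1", "narrow_2")

  score_of <- function(trait, ids) {
    s <- scores[[trait]]
    z <- s$z[match(ids, s$subject_id)]
    if (anyNA(z)) stop("missing '", trait, "' scores for some subjects")
    z
  }
  pcs_of <- function(ids) {
    if (is.null(pcs)) return(NULL)
    pc_cols <- setdiff(names(pcs), "subject_id")[seq_len(n_pcs)]
    m <- as.matrix(pcs[match(ids, pcs$subject_id), pc_cols, drop = FALSE])
    if (anyNA(m)) stop("missing principal components for some subjects")
    colnames(m) <- pc_cols
    m
  }

  one_test <- function(definition, trait, extra_traits = character(),
                       exclude_lithium = FALSE) {
    cmp <- build_comparison(classifications, definition,
                            exclude_lithium_users = exclude_lithium)
    ids <- c(cmp$cases, cmp$controls)
    status <- rep(c(1L, 0L), c(length(cmp$cases), length(cmp$controls)))
    z <- score_of(trait, ids)
    covar <- pcs_of(ids)
    for (et in extra_traits)
      covar <- cbind(covar, stats::setNames(data.frame(score_of(et, ids)), et))
    td <- mean_difference_test(z[status == 1L], z[status == 0L],
                               var_equal = var_equal)
    lg <- fit_logistic(status, z, covariates = covar)
    r2 <- nagelkerke_r2(lg$loglik_full, lg$loglik_base, lg$n)
    qt <- quartile_trend(z, status)
    list(row = data.frame(
      definition = definition, trait = trait,
      covariate_set = if (length(extra_traits))
        paste(extra_traits, collapse = "+") else "none",
      lithium_excluded = exclude_lithium,
      n_cases = lg$n_cases, n_controls = lg$n - lg$n_cases,
      mean_diff = td$estimate, t_p = td$p,
      or = lg$or, or_ci_lower = lg$ci_lower, or_ci_upper = lg$ci_upper,
      logistic_p = lg$p, r2_nagelkerke = r2,
      r2_liability = liability_r2(r2, K = K, P = lg$n_cases / lg$n),
      trend_p = qt$p, stringsAsFactors = FALSE),
      quartiles = cbind(definition = definition, trait = trait, qt$table))
  }

  prim <- list(); quart <- list()
  for (d in definitions) for (tr in traits) {
    res <- one_test(d, tr)
    prim[[paste(d, tr)]] <- res$row
    quart[[paste(d, tr)]] <- res$quartiles
  }
  primary <- do.call(rbind, prim)
  rownames(primary) <- NULL
  primary$t_p_fdr <- bh_fdr(primary$t_p)
  primary$logistic_p_fdr <- bh_fdr(primary$logistic_p)

  sens <- NULL
  if (sensitivity) {
    extra_sets <- list()
    if ("mdd" %in% names(scores)) extra_sets <- c(extra_sets, list("mdd"))
    if ("bip" %in% names(scores)) extra_sets <- c(extra_sets, list("bip"))
    if (all(c("mdd", "bip") %in% names(scores)))
      extra_sets <- c(extra_sets, list(c("mdd", "bip")))
    rows <- list()
    for (d in definitions) for (tr in traits) {
      for (es in extra_sets)
        rows[[length(rows) + 1L]] <- one_test(d, tr, extra_traits = es)$row
      if (tr == "lithium" && any(classifications$lithium_user))
        rows[[length(rows) + 1L]] <-
          one_test(d, tr, exclude_lithium = TRUE)$row
    }
    if (length(rows)) {
      sens <- do.call(rbind, rows)
      rownames(sens) <- NULL
    }
  }

  structure(list(primary = primary, sensitivity = sens,
                 quartiles = do.call(rbind, quart),
                 params = list(traits = traits, n_pcs = n_pcs, K = K,
                               var_equal = var_equal,
                               adjusted = !is.null(pcs))),
            class = "trd_battery")
}

#' @export
print.trd_battery <- function(x, digits = 3, ...) {
  cat("TRD vs non-TRD association battery\n")
  cat(sprintf("  traits: %s | covariates: %s | K = %.2f\n",
              paste(x$params$traits, collapse = ", "),
              if (x$params$adjusted)
                sprintf("first %d PCs", x$params$n_pcs) else "none",
              x$params$K))
  p <- x$primary
  tab <- data.frame(definition = p$definition, trait = p$trait,
                    n = paste0(p$n_cases, "/", p$n_controls),
                    mean_diff = signif(p$mean_diff, digits),
                    P_t = signif(p$t_p, digits),
                    P_t_FDR = signif(p$t_p_fdr, digits),
                    OR = signif(p$or, digits),
                    CI = sprintf("[%.2f, %.2f]", p$or_ci_lower,
                                 p$or_ci_upper),
                    P = signif(p$logistic_p, digits),
                    P_FDR = signif(p$logistic_p_fdr, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.trd_battery <- function(object, ...) {
  p <- object$primary
  cat("Six primary tests (2 traits x 3 definitions), FDR over each family:\n")
  print.trd_battery(object, ...)
  cat("\nVariance explained (Nagelkerke / liability scale at K =",
      object$params$K, "):\n")
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-9s %-8s R2 = %.4f (liability %.4f), P_trend = %.3g\n",
                p$definition[i], p$trait[i], p$r2_nagelkerke[i],
                p$r2_liability[i], p$trend_p[i]))
  if (!is.null(object$sensitivity)) {
    s <- object$sensitivity
    cat(sprintf("\nSensitivity refits: %d (covariate sets: %s%s)\n", nrow(s),
                paste(unique(s$covariate_set), collapse = ", "),
                if (any(s$lithium_excluded)) "; lithium-user exclusion"
                else ""))
  }
  invisible(object)
}

#' @export
as.data.frame.trd_battery <- function(x, ...) {
  p <- x$primary
  if (is.null(x$sensitivity)) return(p)
  s <- x$sensitivity
  s$t_p_fdr <- NA_real_; s$logistic_p_fdr <- NA_real_
  rbind(p, s[names(p)])
}

#' Coefficients (per-SD log odds ratios) of the primary battery tests
#' @param object a `trd_battery`.
#' @param ... unused.
#' @export
coef.trd_battery <- function(object, ...) {
  p <- object$primary
  stats::setNames(log(p$or), paste(p$definition, p$trait, sep = ":"))
}

#' Forest-style plot of the battery odds ratios
#'
#' One point and Wald interval per definition x trait, on the OR scale with a
#' reference line at 1.
#'
#' @param x a `trd_battery`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.trd_battery <- function(x, ...) {
  p <- x$primary
  k <- nrow(p)
  lab <- paste(p$definition, p$trait, sep = " / ")
  rng <- range(c(p$or_ci_lower, p$or_ci_upper, 1))
  op <- graphics::par(mar = c(4, 10, 2, 1)); on.exit(graphics::par(op))
  graphics::plot(p$or, k:1, xlim = rng, ylim = c(0.5, k + 0.5), pch = 19,
                 yaxt = "n", xlab = "OR per SD of PRS", ylab = "",
                 main = "TRD vs non-TRD", ...)
  graphics::segments(p$or_ci_lower, k:1, p$or_ci_upper, k:1)
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::axis(2, at = k:1, labels = lab, las = 1, cex.axis = 0.8)
  invisible(x)
}
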
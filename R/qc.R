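#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on genotype counts at a biallelic site: conditioning on
#' the observed allele counts, sums the probabilities of all heterozygote
#' counts (same parity as the observed one) whose conditional probability does
#' not exceed that of the observed configuration. Monomorphic input returns
#' p = 1. Preferred over the chi-squared approximation because the QC
#' threshold (1e-6) sits far in the tail where the approximation is poor.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (allele1 homozygote,
#'   heterozygote, allele2 homozygote).
#' @return exact two-sided p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)  # modal configuration, p = 1
#' hwe_exact_test(10, 0, 10)   # maximal heterozygote deficit
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n < 1) stop("at least one genotype required")
  n_a <- 2 * n_hom1 + n_het   # copies of allele 1
  n_b <- 2 * n_hom2 + n_het
  if (n_a == 0 || n_b == 0) return(1)
  rare <- min(n_a, n_b)
  # all heterozygote counts with the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(n_het = h | allele counts) up to a common constant:
  # choose(n, h) choose(n - h, (n_a - h)/2) 2^h has log
  logp <- lgamma(n + 1) - lgamma(hets + 1) -
    lgamma((n_a - hets) / 2 + 1) - lgamma((n_b - hets) / 2 + 1) +
    hets * log(2)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  # small relative slack so the observed configuration always counts itself
  sum(p[p <= obs * (1 + 1e-12)])
}

#' Per-variant genotype quality control
#'
#' Applies, in order, the standard marker filters: a lenient call-rate
#' pre-screen (default missingness > 5%), the strict per-variant call-rate
#' threshold (default < 0.98), invariant (monomorphic) markers, exact
#' Hardy-Weinberg disequilibrium tested separately in cases and in controls
#' (removed if either p < 1e-6), case/control differential call rate
#' (> 0.01), and minor allele frequency (< 0.01). A variant failing several
#' filters is attributed to the first in this order.
#'
#' @param G a [geno_matrix()].
#' @param case_status logical or 0/1 vector aligned to `G`'s subjects. If all
#'   subjects share one status, the HWE and differential-call-rate screens use
#'   the whole sample / are skipped respectively.
#' @param callrate_prescreen first-pass call-rate threshold (default 0.95).
#' @param callrate strict call-rate threshold (default 0.98).
#' @param hwe_p HWE exact-test removal threshold (default 1e-6).
#' @param diff_callrate maximum case/control call-rate difference (default 0.01).
#' @param maf minor-allele-frequency threshold (default 0.01).
#' @return list with `genotypes` (the filtered `geno_matrix`) and `report`
#'   (a [qc_report()]).
#' @export
snp_qc <- function(G, case_status, callrate_prescreen = 0.95, callrate = 0.98,
                   hwe_p = 1e-6, diff_callrate = 0.01, maf = 0.01) {
  stopifnot(inherits(G, "geno_matrix"))
  D <- G$dosages
  n <- nrow(D); m <- ncol(D)
  case_status <- as.logical(case_status)
  if (length(case_status) != n)
    stop("case_status must align with subjects")

  called <- !is.na(D)
  cr <- colMeans(called)
  fail <- rep(NA_character_, m)
  mark <- function(idx, why) {
    new <- idx & is.na(fail)
    fail[new] <<- why
    invisible(NULL)
  }
  mark(cr < callrate_prescreen, "callrate_prescreen")
  mark(cr < callrate, "callrate")

  # invariant = monomorphic: only one allele observed among called genotypes
  p1 <- allele1_freq(G)
  mark(!is.finite(p1) | p1 == 0 | p1 == 1, "invariant")

  hwe_min_p <- vapply(seq_len(m), function(j) {
    ps <- vapply(c(TRUE, FALSE), function(grp) {
      x <- D[case_status == grp, j]
      x <- x[!is.na(x)]
      if (!length(x)) return(1)
      hwe_exact_test(sum(x == 2L), sum(x == 1L), sum(x == 0L))
    }, numeric(1))
    min(ps)
  }, numeric(1))
  mark(hwe_min_p < hwe_p, "hwe")

  if (any(case_status) && any(!case_status)) {
    cr_case <- colMeans(called[case_status, , drop = FALSE])
    cr_ctrl <- colMeans(called[!case_status, , drop = FALSE])
    mark(abs(cr_case - cr_ctrl) > diff_callrate, "diff_callrate")
  }

  mark(geno_maf(G) < maf, "maf")

  keep <- is.na(fail)
  if (!any(keep)) stop("all variants removed by SNP QC")
  removed_by <- table(factor(fail, levels = c("callrate_prescreen", "callrate",
                                              "invariant", "hwe",
                                              "diff_callrate", "maf")))
  rep <- qc_report("snp_qc", "variant", m,
                   removed_by = stats::setNames(as.integer(removed_by),
                                                names(removed_by)),
                   retained = G$variants$id[keep],
                   params = list(callrate_prescreen = callrate_prescreen,
                                 callrate = callrate, hwe_p = hwe_p,
                                 diff_callrate = diff_callrate, maf = maf))
  list(genotypes = G[, keep], report = rep)
}

#' Per-sample quality control
#'
#' Removes samples with call rate below `callrate`; computes each sample's
#' autosomal inbreeding coefficient F = 1 - observed het / expected het
#' (expected heterozygosity from the per-variant allele frequencies over
#' called genotypes) and removes |F| > `fhet`; and removes sex mismatches.
#' Sex is inferred from the X-chromosome heterozygosity rate: male if
#' below `male_max_xhet`, female if above `female_min_xhet`, ambiguous
#' otherwise (ambiguous samples are never removed for sex).
#'
#' @param G a [geno_matrix()].
#' @param reported_sex character vector, `"male"`/`"female"` (NA allowed),
#'   aligned to subjects.
#' @param x_het_rate numeric vector of X-marker heterozygosity rates.
#' @param callrate sample call-rate threshold (default 0.98).
#' @param fhet heterozygosity F bound (default 0.20).
#' @param male_max_xhet,female_min_xhet sex-inference cutoffs (0.02 / 0.20).
#' @return list with `genotypes` (filtered) and `report`.
#' @export
sample_qc <- function(G, reported_sex, x_het_rate, callrate = 0.98,
                      fhet = 0.20, male_max_xhet = 0.02,
                      female_min_xhet = 0.20) {
  stopifnot(inherits(G, "geno_matrix"))
  D <- G$dosages
  n <- nrow(D)
  stopifnot(length(reported_sex) == n, length(x_het_rate) == n)

  cr <- rowMeans(!is.na(D))
  p <- allele1_freq(G)
  exp_het_j <- 2 * p * (1 - p)
  het <- D == 1L
  obs_het <- rowSums(het, na.rm = TRUE)
  exp_het <- (!is.na(D)) %*% exp_het_j
  f <- ifelse(exp_het > 0, 1 - obs_het / as.vector(exp_het), 0)

  inferred <- ifelse(x_het_rate < male_max_xhet, "male",
                     ifelse(x_het_rate > female_min_xhet, "female", NA))
  mismatch <- !is.na(inferred) & !is.na(reported_sex) &
    inferred != reported_sex

  fail <- rep(NA_character_, n)
  mark <- function(idx, why) {
    new <- idx & is.na(fail)
    fail[new] <<- why
  }
  mark(cr < callrate, "callrate")
  mark(abs(f) > fhet, "fhet")
  mark(mismatch, "sex_mismatch")

  keep <- is.na(fail)
  if (!any(keep)) stop("all samples removed by sample QC")
  removed_by <- table(factor(fail, levels = c("callrate", "fhet",
                                              "sex_mismatch")))
  rep <- qc_report("sample_qc", "sample", n,
                   removed_by = stats::setNames(as.integer(removed_by),
                                                names(removed_by)),
                   retained = G$subject_ids[keep],
                   params = list(callrate = callrate, fhet = fhet,
                                 male_max_xhet = male_max_xhet,
                                 female_min_xhet = female_min_xhet),
                   details = data.frame(subject_id = G$subject_ids,
                                        call_rate = cr, fhet = as.vector(f),
                                        inferred_sex = inferred,
                                        stringsAsFactors = FALSE))
  list(genotypes = G[keep, ], report = rep)
}

#' Pairwise IBD estimation and relatedness pruning
#'
#' Estimates pairwise pi-hat (proportion of the genome shared
#' identical-by-descent) with the method-of-moments inversion of
#' identity-by-state counts: per-variant IBS probabilities given IBD state are
#' computed from allele frequencies estimated in the sample, P(IBD = 0, 1, 2)
#' are solved step-up, and pi-hat = P(IBD=1)/2 + P(IBD=2). For each pair with
#' pi-hat above the threshold, one member is removed: the one with the lower
#' call rate, ties broken by input order (the later subject is dropped).
#'
#' @param G a [geno_matrix()], ideally already variant-QC'd.
#' @param pihat_threshold relatedness cutoff (default 0.2).
#' @return list with `genotypes` (pruned), `report`, and `pihat` (data.frame
#'   of flagged pairs: `id1`, `id2`, `pihat`).
#' @export
relatedness_prune <- function(G, pihat_threshold = 0.2) {
  stopifnot(inherits(G, "geno_matrix"))
  n <- nrow(G$dosages)
  if (n < 2) stop("at least two samples required")
  PH <- pihat_matrix(G)
  flag <- which(upper.tri(PH) & PH > pihat_threshold, arr.ind = TRUE)
  pairs <- data.frame(id1 = G$subject_ids[flag[, 1]],
                      id2 = G$subject_ids[flag[, 2]],
                      pihat = PH[flag])
  cr <- rowMeans(!is.na(G$dosages))
  drop <- logical(n)
  if (nrow(flag)) {
    # greedy: process pairs in order, drop one member of each still-intact pair
    for (k in seq_len(nrow(flag))) {
      i <- flag[k, 1]; j <- flag[k, 2]
      if (drop[i] || drop[j]) next
      drop[if (cr[i] < cr[j]) i else j] <- TRUE
    }
  }
  keep <- !drop
  rep <- qc_report("relatedness", "sample", n,
                   removed_by = c(related = sum(drop)),
                   retained = G$subject_ids[keep],
                   params = list(pihat_threshold = pihat_threshold))
  list(genotypes = G[keep, ], report = rep, pihat = pairs)
}

#' Pairwise pi-hat matrix
#'
#' The method-of-moments IBD estimator underlying [relatedness_prune()],
#' exposed for inspection. Allele frequencies default to estimates from the
#' supplied sample, which is adequate for the sample sizes the pipeline
#' works at; for small subsets pass frequencies estimated on a larger sample
#' via `freqs`, since the moment inversion is sensitive to frequency error.
#' Missing genotypes are handled pairwise (a variant contributes to a pair
#' only when both members are called).
#'
#' @param G a [geno_matrix()].
#' @param freqs optional per-variant allele1 frequencies; NULL estimates them
#'   from `G`.
#' @return symmetric n x n matrix of pi-hat estimates (diagonal 1).
#' @export
pihat_matrix <- function(G, freqs = NULL) {
  D <- G$dosages
  n <- nrow(D)
  p <- if (is.null(freqs)) allele1_freq(G) else freqs
  q <- 1 - p
  # conditional IBS probabilities per variant
  c0_ibs0 <- 2 * p^2 * q^2
  c0_ibs1 <- 4 * p^3 * q + 4 * p * q^3
  c0_ibs2 <- p^4 + q^4 + 4 * p^2 * q^2
  c1_ibs1 <- 2 * p^2 * q + 2 * p * q^2
  c1_ibs2 <- p^3 + q^3 + p^2 * q + p * q^2

  V <- (!is.na(D)) * 1
  A0 <- (!is.na(D) & D == 0L) * 1
  A1 <- (!is.na(D) & D == 1L) * 1
  A2 <- (!is.na(D) & D == 2L) * 1

  # observed IBS counts per pair
  N_ibs0 <- A0 %*% t(A2); N_ibs0 <- N_ibs0 + t(N_ibs0)
  N_ibs2 <- A0 %*% t(A0) + A1 %*% t(A1) + A2 %*% t(A2)
  N_valid <- V %*% t(V)
  N_ibs1 <- N_valid - N_ibs0 - N_ibs2

  # per-pair sums of conditional probabilities over jointly called variants
  wsum <- function(w) (V * rep(w, each = n)) %*% t(V)
  S0_0 <- wsum(c0_ibs0); S0_1 <- wsum(c0_ibs1); S0_2 <- wsum(c0_ibs2)
  S1_1 <- wsum(c1_ibs1); S1_2 <- wsum(c1_ibs2)

  P0 <- N_ibs0 / S0_0
  P1 <- (N_ibs1 - P0 * S0_1) / S1_1
  P2 <- (N_ibs2 - P0 * S0_2 - P1 * S1_2) / N_valid
  PH <- P1 / 2 + P2
  PH[!is.finite(PH)] <- 0
  PH <- pmin(pmax(PH, 0), 1)
  diag(PH) <- 1
  dimnames(PH) <- list(G$subject_ids, G$subject_ids)
  PH
}

#' Flag ancestry outliers by PCA projection onto a reference panel
#'
#' Computes the top two principal components of the standardized reference
#' genotypes, projects the study samples onto the reference SNP loadings, and
#' flags any study sample whose PC1 or PC2 lies more than `sd_threshold`
#' standard deviations from the mean of the reference target population
#' (the population named by `target_population`).
#'
#' @param G study [geno_matrix()].
#' @param reference reference [geno_matrix()] sharing variants with `G`.
#' @param ref_populations character vector of population labels aligned to the
#'   reference subjects.
#' @param target_population the reference population anchoring the mean/SD
#'   envelope (default the most frequent label).
#' @param sd_threshold outlyingness cutoff in reference-population SDs
#'   (default 6).
#' @param min_shared minimum number of shared variants required (default 100).
#' @return list with `genotypes` (outliers removed), `report`, and
#'   `projection` (data.frame of study PC coordinates and flags).
#' @export
ancestry_outliers <- function(G, reference, ref_populations,
                              target_population = NULL, sd_threshold = 6,
                              min_shared = 100) {
  stopifnot(inherits(G, "geno_matrix"), inherits(reference, "geno_matrix"))
  shared <- intersect(G$variants$id, reference$variants$id)
  if (length(shared) < min_shared)
    stop("fewer than ", min_shared, " variants shared with the reference")
  Gs <- G[, match(shared, G$variants$id)]
  Rs <- reference[, match(shared, reference$variants$id)]
  if (is.null(target_population))
    target_population <- names(sort(table(ref_populations),
                                    decreasing = TRUE))[1]

  R <- Rs$dosages
  p <- colMeans(R, na.rm = TRUE) / 2
  sdv <- sqrt(2 * p * (1 - p))
  informative <- is.finite(sdv) & sdv > 0
  if (sum(informative) < 2) stop("fewer than 2 informative dimensions")
  std <- function(M) {
    M <- M[, informative, drop = FALSE]
    M <- sweep(M, 2, 2 * p[informative], "-")
    M <- sweep(M, 2, sdv[informative], "/")
    M[is.na(M)] <- 0
    M
  }
  Rstd <- std(R)
  sv <- svd(Rstd, nu = 0, nv = 2)
  load <- sv$v  # SNP loadings for PC1-2
  ref_pc <- Rstd %*% load
  study_pc <- std(Gs$dosages) %*% load

  tgt <- ref_populations == target_population
  mu <- colMeans(ref_pc[tgt, , drop = FALSE])
  sdr <- apply(ref_pc[tgt, , drop = FALSE], 2, stats::sd)
  z <- sweep(sweep(study_pc, 2, mu, "-"), 2, sdr, "/")
  flagged <- abs(z[, 1]) > sd_threshold | abs(z[, 2]) > sd_threshold

  keep <- !flagged
  rep <- qc_report("ancestry", "sample", nrow(G$dosages),
                   removed_by = c(ancestry_outlier = sum(flagged)),
                   retained = G$subject_ids[keep],
                   params = list(sd_threshold = sd_threshold,
                                 target_population = target_population,
                                 n_shared = length(shared)))
  proj <- data.frame(subject_id = G$subject_ids, pc1 = study_pc[, 1],
                     pc2 = study_pc[, 2], flagged = flagged)
  geno <- if (any(keep)) G[keep, ] else G[0, ]
  list(genotypes = geno, report = rep, projection = proj)
}
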
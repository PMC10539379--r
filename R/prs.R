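#' Construct a variant weight table
#'
#' Per-variant effect-allele weights for polygenic scoring, as produced by an
#' LD-rescaling method applied to GWAS summary statistics. The weight is the
#' per-allele effect on the score; `freq` is the effect-allele frequency in
#' the source GWAS and `info` the imputation quality.
#'
#' @param id,chr,pos,effect_allele,other_allele,freq,weight,info parallel
#'   per-variant vectors.
#' @return data.frame of class `weight_table`.
#' @export
weight_table <- function(id, chr, pos, effect_allele, other_allele,
                         freq, weight, info = rep(1, length(id))) {
  out <- data.frame(id = as.character(id), chr = as.character(chr),
                    pos = as.integer(pos),
                    effect_allele = as.character(effect_allele),
                    other_allele = as.character(other_allele),
                    freq = as.numeric(freq), weight = as.numeric(weight),
                    info = as.numeric(info), stringsAsFactors = FALSE)
  if (any(out$freq <= 0 | out$freq >= 1))
    stop("effect-allele frequencies must lie in (0, 1)")
  if (any(out$info < 0 | out$info > 1))
    stop("info scores must lie in [0, 1]")
  class(out) <- c("weight_table", "data.frame")
  out
}

strand_ambiguous <- function(a1, a2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  a2 == comp[a1]
}

#' Filter a weight table for polygenic scoring
#'
#' Applies, in order, the standard pre-scoring filters to the summary-statistic
#' weights: effect-allele frequency outside \[`maf`, 1 - `maf`\] (minor-allele
#' frequency below the cutoff *in the source GWAS*); imputation INFO below
#' `info`; duplicated variant ids (all copies removed); strand-ambiguous A/T
#' and C/G pairs; and variants inside the extended MHC region
#' (chr6:28-34 Mb, GRCh37 coordinates, both ends inclusive). The surviving
#' weights are then intersected with the target genotypes by variant id, with
#' allele reconciliation: when the table's effect allele equals the target's
#' allele2 (and the other allele equals allele1) the weight's sign is flipped
#' so that scoring over allele1 dosages is effect-allele consistent;
#' irreconcilable allele pairs are dropped.
#'
#' @param weights a [weight_table()].
#' @param G target [geno_matrix()].
#' @param maf source-GWAS minor-allele-frequency cutoff (default 0.1).
#' @param info INFO cutoff (default 0.9).
#' @param mhc_chr,mhc_range MHC exclusion window (chr "6", 28e6-34e6).
#' @param whitelist optional character vector of variant ids to intersect with
#'   (e.g. a HapMap3 id list); NULL disables the filter.
#' @return list with `weights` (the filtered, allele-aligned `weight_table`)
#'   and `report` (a [qc_report()] on the variant axis).
#' @export
filter_weights <- function(weights, G, maf = 0.1, info = 0.9,
                           mhc_chr = "6", mhc_range = c(28e6, 34e6),
                           whitelist = NULL) {
  stopifnot(inherits(weights, "weight_table"), inherits(G, "geno_matrix"))
  if (!nrow(weights)) stop("empty weight table")
  m <- nrow(weights)
  fail <- rep(NA_character_, m)
  mark <- function(idx, why) {
    new <- idx & is.na(fail)
    fail[new] <<- why
  }
  mark(weights$freq < maf | weights$freq > 1 - maf, "maf")
  mark(weights$info < info, "info")
  dup <- weights$id %in% weights$id[duplicated(weights$id)]
  mark(dup, "duplicate_id")
  mark(strand_ambiguous(weights$effect_allele, weights$other_allele),
       "strand_ambiguous")
  mark(weights$chr == mhc_chr & weights$pos >= mhc_range[1] &
         weights$pos <= mhc_range[2], "mhc")
  if (!is.null(whitelist))
    mark(!(weights$id %in% whitelist), "not_in_whitelist")

  w <- weights[is.na(fail), , drop = FALSE]

  # intersect with target variants, reconciling alleles
  gi <- match(w$id, G$variants$id)
  absent <- is.na(gi)
  same <- !absent & w$effect_allele == G$variants$allele1[gi] &
    w$other_allele == G$variants$allele2[gi]
  flipped <- !absent & w$effect_allele == G$variants$allele2[gi] &
    w$other_allele == G$variants$allele1[gi]
  irrec <- !absent & !same & !flipped

  idx_in_full <- which(is.na(fail))
  mark_full <- function(sub_idx, why) {
    i <- idx_in_full[sub_idx]
    new <- is.na(fail[i])
    fail[i[new]] <<- why
  }
  mark_full(which(absent), "absent_from_target")
  mark_full(which(irrec), "allele_mismatch")

  keep <- same | flipped
  out <- w[keep, , drop = FALSE]
  fl <- flipped[keep]
  # express weights on the allele1-dosage scale of the target
  out$weight[fl] <- -out$weight[fl]
  out$freq[fl] <- 1 - out$freq[fl]
  tmp <- out$effect_allele[fl]
  out$effect_allele[fl] <- out$other_allele[fl]
  out$other_allele[fl] <- tmp
  if (!nrow(out)) stop("no weight-table variants usable in the target")

  removed_by <- table(factor(fail, levels = c("maf", "info", "duplicate_id",
                                              "strand_ambiguous", "mhc",
                                              "not_in_whitelist",
                                              "absent_from_target",
                                              "allele_mismatch")))
  rep <- qc_report("filter_weights", "variant", m,
                   removed_by = stats::setNames(as.integer(removed_by),
                                                names(removed_by)),
                   retained = out$id,
                   params = list(maf = maf, info = info, mhc_chr = mhc_chr,
                                 mhc_range = mhc_range,
                                 whitelist = !is.null(whitelist)))
  class(out) <- c("weight_table", "data.frame")
  list(weights = out, report = rep)
}

#' Compute polygenic scores
#'
#' Raw score per subject = sum over variants of weight x effect-allele dosage.
#' After [filter_weights()] the weights are expressed on the target's allele1
#' dosages, so the sum runs directly over the dosage matrix. Missing dosages
#' are handled per `missing_policy`: `"impute_freq"` (default) replaces a
#' missing call with twice the effect-allele frequency, the usual convention
#' for scoring imputed data; `"omit_rescale"` omits missing variants and
#' rescales the score by the ratio of total to observed weight magnitude.
#' The standardized score is (raw - sample mean) / sample SD; zero variance
#' is an error, never silently propagated.
#'
#' @param G a [geno_matrix()].
#' @param weights a filtered, allele-aligned [weight_table()] whose ids are a
#'   subset of `G`'s variants.
#' @param missing_policy `"impute_freq"` or `"omit_rescale"`.
#' @param trait label carried into the result (default "trait").
#' @return data.frame of class `score_vector`: `subject_id`, `raw`, `z`,
#'   `trait`.
#' @export
prs_score <- function(G, weights, missing_policy = c("impute_freq",
                                                     "omit_rescale"),
                      trait = "trait") {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(G, "geno_matrix"), inherits(weights, "weight_table"))
  j <- match(weights$id, G$variants$id)
  if (anyNA(j)) stop("weights reference variants absent from the genotypes")
  D <- G$dosages[, j, drop = FALSE]
  w <- weights$weight

  if (missing_policy == "impute_freq") {
    if (anyNA(D)) {
      fill <- matrix(rep(2 * weights$freq, each = nrow(D)), nrow = nrow(D))
      D <- ifelse(is.na(D), fill, D)
    }
    raw <- as.vector(D %*% w)
  } else {
    obs <- !is.na(D)
    if (any(rowSums(obs) == 0L))
      stop("some subjects have zero usable variants under the omit policy")
    D0 <- D; D0[!obs] <- 0
    raw <- as.vector(D0 %*% w)
    wa <- abs(w)
    denom <- as.vector(obs %*% wa)
    raw <- raw * sum(wa) / denom
  }

  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0)
    stop("polygenic score has zero variance; cannot standardize")
  out <- data.frame(subject_id = G$subject_ids, raw = raw,
                    z = (raw - mean(raw)) / s, trait = trait,
                    stringsAsFactors = FALSE)
  class(out) <- c("score_vector", "data.frame")
  out
}
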
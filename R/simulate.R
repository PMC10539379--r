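#' Configuration of the synthetic study generator
#'
#' Houses every knob of the simulated register + genotype study. The defaults
#' reproduce the design of the Swedish MDD case sample the pipeline targets:
#' 4572 MDD cases across an ECT-referral cohort, an internet-CBT cohort, and a
#' population-register cohort (1922/964/1686); per-SD odds ratios of 1.12
#' (lithium-response score) and 0.98 (antidepressant-response score) on TRD
#' status; an overall TRD rate of 0.44 among analyzable cases; episode gap
#' 120 days and adequacy 42 days; and an antidepressant-adequacy profile of
#' ECT cases (5.8% no antidepressant before ECT, 10.6% inadequate only,
#' 22.8% exactly one adequate drug, 60.8% two or more) with 33.5% of non-ECT
#' cases carrying three or more adequate drugs and 28% of TRD cases using
#' lithium.
#'
#' @param n_subjects number of MDD cases (default 4572).
#' @param cohort_fractions three proportions summing to 1 (ECT-referral,
#'   psychotherapy, population cohort).
#' @param n_snps number of autosomal variants (default 2000).
#' @param maf_range allele-frequency range, each end in (0, 0.5].
#' @param or_per_sd_lithium,or_per_sd_antidep per-SD odds ratios linking the
#'   true standardized scores to TRD status.
#' @param base_trd_rate TRD probability at score zero (default 0.44).
#' @param gap_days,adequate_days episode construction and adequacy rules.
#' @param missing_rate fraction of genotype calls masked missing (default
#'   0.002).
#' @param n_planted_per_filter number of weight-table variants deliberately
#'   generated to violate each scoring filter (low MAF, low INFO,
#'   strand-ambiguous, MHC, duplicate id); default 12 each.
#' @param ect_profile four probabilities (no antidepressant before ECT /
#'   inadequate only / exactly one adequate / two or more adequate) summing
#'   to 1 over ECT-treated subjects.
#' @param nonect_many_adequate_rate fraction of non-ECT subjects with >= 3
#'   adequate antidepressants (excluded from narrow comparisons).
#' @param lithium_fraction fraction of TRD subjects with lithium records.
#' @param female_fraction reported-female fraction (default 0.6).
#' @param sex_mismatch_rate fraction of subjects whose reported sex is flipped
#'   relative to the genetically inferred one.
#' @param ancestry_outlier_rate fraction of subjects drawn from a second
#'   population with shifted allele frequencies.
#' @param ancestry_freq_shift allele-frequency shift of the second population.
#' @param study_days register window length in days (default 4700).
#' @param seed integer seed; all stages derive child seeds from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 4572,
                       cohort_fractions = c(ect = 1922, psychotherapy = 964,
                                            population = 1686) / 4572,
                       n_snps = 2000,
                       maf_range = c(0.05, 0.5),
                       or_per_sd_lithium = 1.12,
                       or_per_sd_antidep = 0.98,
                       base_trd_rate = 0.44,
                       gap_days = 120,
                       adequate_days = 42,
                       missing_rate = 0.002,
                       n_planted_per_filter = 12,
                       ect_profile = c(none = 0.058, inadequate = 0.106,
                                       one_adequate = 0.228,
                                       two_plus_adequate = 0.608),
                       nonect_many_adequate_rate = 0.335,
                       lithium_fraction = 0.28,
                       female_fraction = 0.6,
                       sex_mismatch_rate = 0.003,
                       ancestry_outlier_rate = 0.01,
                       ancestry_freq_shift = 0.2,
                       study_days = 4700,
                       seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_subjects >= 1, n_snps >= 1,
              abs(sum(cohort_fractions) - 1) < 1e-9,
              all(cohort_fractions >= 0),
              length(maf_range) == 2, all(maf_range > 0),
              all(maf_range <= 0.5), maf_range[1] <= maf_range[2],
              or_per_sd_lithium > 0, or_per_sd_antidep > 0,
              base_trd_rate >= 0, base_trd_rate <= 1,
              gap_days > 0, adequate_days >= 0,
              missing_rate >= 0, missing_rate <= 1,
              abs(sum(ect_profile) - 1) < 1e-9, all(ect_profile >= 0),
              nonect_many_adequate_rate >= 0, nonect_many_adequate_rate <= 1,
              lithium_fraction >= 0, lithium_fraction <= 1,
              female_fraction >= 0, female_fraction <= 1,
              sex_mismatch_rate >= 0, sex_mismatch_rate <= 1,
              ancestry_outlier_rate >= 0, ancestry_outlier_rate <= 1,
              study_days > 0, seed == as.integer(seed))
  })
  if (5 * cfg$n_planted_per_filter > cfg$n_snps)
    stop("n_snps smaller than the number of deliberately invalid variants")
  if (cfg$adequate_days > cfg$study_days / 4)
    stop("adequate_days exceeds the longest generatable episode span ",
         "under study_days")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

# stable child-seed derivation so stages can be re-run in isolation
child_seed <- function(seed, stage) {
  stage_n <- sum(utf8ToInt(stage))
  as.integer((as.numeric(seed) %% 100003) * 10007 + stage_n * 101 + 7) %%
    2147483647L
}

#' Simulate genotypes and per-trait weight tables
#'
#' Draws a per-variant allele frequency from `maf_range`, then 0/1/2 dosages
#' binomially per subject, independent across variants (weights are treated as
#' already LD-rescaled, so no LD is simulated). A configured fraction of
#' subjects is drawn from a second population with shifted allele frequencies
#' (the ancestry-outlier construct). One weight table per trait is generated
#' with `n_planted_per_filter` variants per scoring filter deliberately
#' violating it (effect-allele frequency < 0.1, INFO < 0.9, A/T or C/G
#' alleles, positions inside chr6:28-34 Mb, duplicated ids) so every filter is
#' exercised downstream; the planted rows are recorded and excluded from the
#' true scores. Finally `missing_rate` of calls is masked missing.
#'
#' @param config a [sim_config()].
#' @param traits names of the weight tables to generate.
#' @return list with `genotypes` (a [geno_matrix()], missingness applied),
#'   `complete` (the same matrix before masking), `weights` (named list of
#'   [weight_table()]), `planted` (data.frame id/reason), `ancestry_outlier`
#'   (logical per subject), and `freqs` (the generating allele frequencies).
#' @export
simulate_genotypes <- function(config,
                               traits = c("lithium", "antidep", "mdd",
                                          "bip")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "genotypes"))
  n <- config$n_subjects; m <- config$n_snps
  k <- config$n_planted_per_filter

  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])

  planted_idx <- if (k > 0) matrix(seq_len(5 * k), nrow = k) else
    matrix(integer(), nrow = 0, ncol = 5)
  v_maf <- planted_idx[, 1]; v_info <- planted_idx[, 2]
  v_amb <- planted_idx[, 3]; v_mhc <- planted_idx[, 4]
  v_dup <- planted_idx[, 5]

  chr <- as.character(sample(c(1:5, 7:22), m, replace = TRUE))
  pos <- sample.int(2e8, m, replace = TRUE)
  chr[v_mhc] <- "6"
  pos[v_mhc] <- sample(28e6:34e6, length(v_mhc))
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
  pick <- sample.int(4, m, replace = TRUE)
  a1 <- pairs[pick, 1]; a2 <- pairs[pick, 2]
  amb_pairs <- rbind(c("A", "T"), c("C", "G"))
  amb_pick <- sample.int(2, length(v_amb), replace = TRUE)
  a1[v_amb] <- amb_pairs[amb_pick, 1]; a2[v_amb] <- amb_pairs[amb_pick, 2]
  ids <- sprintf("rs%07d", sample.int(9999999, m))

  outlier <- stats::runif(n) < config$ancestry_outlier_rate
  shift_dir <- sample(c(-1, 1), m, replace = TRUE)
  p2 <- pmin(pmax(p + shift_dir * config$ancestry_freq_shift, 0.01), 0.99)
  D <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    pj <- ifelse(outlier, p2[j], p[j])
    D[, j] <- stats::rbinom(n, 2L, pj)
  }
  subjects <- sprintf("S%05d", seq_len(n))
  variants <- data.frame(id = ids, chr = chr, pos = pos,
                         allele1 = a1, allele2 = a2,
                         stringsAsFactors = FALSE)
  complete <- geno_matrix(D, variants, subjects)

  weights <- list(); planted <- NULL
  for (tr in traits) {
    w <- stats::rnorm(m, 0, 1 / sqrt(m))
    freq <- round(pmin(pmax(p + stats::rnorm(m, 0, 0.01), 0.02), 0.98), 4)
    info <- round(stats::runif(m, 0.95, 1), 4)
    freq[v_maf] <- round(stats::runif(length(v_maf), 0.01, 0.09), 4)
    info[v_info] <- round(stats::runif(length(v_info), 0.3, 0.89), 4)
    wt <- weight_table(ids, chr, pos, a1, a2, freq, w, info)
    if (length(v_dup)) wt <- rbind(wt, wt[v_dup, , drop = FALSE])
    class(wt) <- c("weight_table", "data.frame")
    weights[[tr]] <- wt
    if (is.null(planted)) {
      planted <- data.frame(
        id = ids[c(v_maf, v_info, v_amb, v_mhc, v_dup)],
        reason = rep(c("maf", "info", "strand_ambiguous", "mhc",
                       "duplicate_id"),
                     times = c(length(v_maf), length(v_info), length(v_amb),
                               length(v_mhc), length(v_dup))),
        stringsAsFactors = FALSE)
    }
  }

  G <- complete
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    Dm <- G$dosages
    Dm[mask] <- NA_integer_
    G <- geno_matrix(Dm, variants, subjects)
  }
  list(genotypes = G, complete = complete, weights = weights,
       planted = planted, ancestry_outlier = outlier, freqs = p)
}

#' Simulate true scores and TRD status
#'
#' The true per-trait score is the weighted allele count over the non-planted
#' weight-table variants (missing calls imputed to twice the allele
#' frequency), standardized to mean 0 / SD 1 within the simulated sample.
#' TRD status is Bernoulli with
#' logit(p) = logit(base_trd_rate) + log(or_lithium) z_lithium +
#' log(or_antidep) z_antidep: the generator inverts the association model the
#' pipeline later fits.
#'
#' @param genotypes a [geno_matrix()].
#' @param weights named list of [weight_table()]s containing at least
#'   `lithium` and `antidep`.
#' @param config a [sim_config()].
#' @param planted optional data.frame of planted invalid weight rows to
#'   exclude from the true scores.
#' @return truth data.frame: `subject_id`, `z_lithium`, `z_antidep`, `trd`.
#' @export
simulate_phenotypes <- function(genotypes, weights, config, planted = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("lithium", "antidep") %in% names(weights)))
    stop("weights must contain 'lithium' and 'antidep' tables")
  set.seed(child_seed(config$seed, "phenotypes"))
  z_of <- function(wt) {
    if (!nrow(wt)) stop("empty weight table")
    if (!is.null(planted)) wt <- wt[!(wt$id %in% planted$id), , drop = FALSE]
    wt <- wt[!duplicated(wt$id), , drop = FALSE]
    wt <- wt[wt$id %in% genotypes$variants$id, , drop = FALSE]
    class(wt) <- c("weight_table", "data.frame")
    sc <- prs_score(genotypes, wt, missing_policy = "impute_freq")
    sc$z
  }
  z_li <- z_of(weights$lithium)
  z_ad <- z_of(weights$antidep)
  if (config$base_trd_rate == 0) {
    trd <- rep(0L, config$n_subjects)
  } else if (config$base_trd_rate == 1) {
    trd <- rep(1L, config$n_subjects)
  } else {
    eta <- stats::qlogis(config$base_trd_rate) +
      log(config$or_per_sd_lithium) * z_li +
      log(config$or_per_sd_antidep) * z_ad
    trd <- stats::rbinom(length(eta), 1L, stats::plogis(eta))
  }
  data.frame(subject_id = genotypes$subject_ids, z_lithium = z_li,
             z_antidep = z_ad, trd = trd, stringsAsFactors = FALSE)
}

# antidepressant ATC codes the generator draws from (SSRIs, SNRIs, TCAs, ...)
ANTIDEP_ATC <- c("N06AB03", "N06AB04", "N06AB05", "N06AB06", "N06AB10",
                 "N06AX11", "N06AX16", "N06AX21", "N06AA04", "N06AA09",
                 "N06AA10", "N06AG02")
LITHIUM_ATC <- "N05AN01"

# one dispensing chain: dates from `start` to exactly `start + span`, all
# consecutive gaps <= gap_days (span 0 = single dispense)
gen_chain <- function(start, span, gap_days) {
  if (span <= 0L) return(start)
  gaps <- integer()
  while (sum(gaps) < span)
    gaps <- c(gaps, sample(seq(21L, min(84L, gap_days)), 1L))
  cum <- cumsum(gaps)
  start + c(0L, cum[cum < span], span)
}

#' Simulate prescription and ECT histories from true TRD status
#'
#' TRD subjects receive a first ECT date and an antidepressant history drawn
#' from the configured adequacy profile: two or more distinct N06A drugs with
#' adequate (>= `adequate_days`) dispensing chains before the ECT date, exactly
#' one adequate drug, inadequate chains only, or no antidepressant at all —
#' the latter three being the register noise that makes broad and narrow case
#' counts differ. A configured fraction of TRD subjects also receives lithium
#' (N05AN01) records. Non-TRD subjects get no ECT; most carry 1-2
#' antidepressants (adequate or not), and a configured fraction carries >= 3
#' adequate drugs (excluded from narrow comparisons downstream).
#'
#' @param truth data.frame from [simulate_phenotypes()].
#' @param config a [sim_config()].
#' @return list with `prescriptions`, `ect_events`, and `intended` (per
#'   subject: the generator's intended labels and lithium flag, for round-trip
#'   testing).
#' @export
simulate_treatment_history <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(truth))
  set.seed(child_seed(config$seed, "treatment"))
  gap <- config$gap_days
  adq <- config$adequate_days
  horizon <- config$study_days
  ect_min <- max(4L * adq + 120L, 400L)
  if (ect_min >= horizon)
    stop("study_days too short to place adequate episodes before ECT")

  rx <- list(); ect <- list(); intended <- list()
  profile_levels <- c("none", "inadequate", "one_adequate",
                      "two_plus_adequate")
  for (i in seq_len(nrow(truth))) {
    sid <- truth$subject_id[i]
    drugs <- sample(ANTIDEP_ATC)
    recs <- NULL
    lith <- FALSE
    if (truth$trd[i] == 1L) {
      ect_day <- sample(seq(ect_min, horizon), 1L)
      cat_i <- sample(profile_levels, 1L, prob = config$ect_profile)
      n_adq <- switch(cat_i, none = 0L, inadequate = 0L, one_adequate = 1L,
                      two_plus_adequate = sample(2:4, 1L))
      n_inadq <- switch(cat_i, none = 0L, inadequate = sample(1:2, 1L),
                        one_adequate = sample(0:1, 1L),
                        two_plus_adequate = 0L)
      d <- 0L
      for (a in seq_len(n_adq)) {
        d <- d + 1L
        span <- sample(seq(adq, min(3L * adq + 60L, ect_day - 2L)), 1L)
        start <- sample(seq(1L, ect_day - span - 1L), 1L)
        recs <- rbind(recs, data.frame(
          subject_id = sid, atc_code = drugs[d],
          dispense_date = gen_chain(start, span, gap)))
      }
      for (a in seq_len(n_inadq)) {
        d <- d + 1L
        start <- sample(seq(1L, ect_day - 2L), 1L)
        recs <- rbind(recs, data.frame(
          subject_id = sid, atc_code = drugs[d], dispense_date = start))
      }
      if (stats::runif(1) < config$lithium_fraction) {
        lith <- TRUE
        start <- sample(seq(1L, horizon - 60L), 1L)
        recs <- rbind(recs, data.frame(
          subject_id = sid, atc_code = LITHIUM_ATC,
          dispense_date = gen_chain(start, 60L, gap)))
      }
      ect[[sid]] <- data.frame(subject_id = sid, date = ect_day)
      intended[[sid]] <- data.frame(
        subject_id = sid, broad = "TRD",
        narrow1 = if (n_adq >= 1L) "TRD" else "excluded",
        narrow2 = if (n_adq >= 2L) "TRD" else "excluded",
        lithium_user = lith, stringsAsFactors = FALSE)
    } else {
      many <- stats::runif(1) < config$nonect_many_adequate_rate
      n_adq <- if (many) sample(3:4, 1L) else sample(0:2, 1L)
      n_inadq <- if (n_adq == 0L) sample(1:2, 1L) else sample(0:1, 1L)
      d <- 0L
      for (a in seq_len(n_adq)) {
        d <- d + 1L
        span <- sample(seq(adq, 3L * adq + 60L), 1L)
        start <- sample(seq(1L, horizon - span - 1L), 1L)
        recs <- rbind(recs, data.frame(
          subject_id = sid, atc_code = drugs[d],
          dispense_date = gen_chain(start, span, gap)))
      }
      for (a in seq_len(n_inadq)) {
        d <- d + 1L
        start <- sample(seq(1L, horizon - 1L), 1L)
        recs <- rbind(recs, data.frame(
          subject_id = sid, atc_code = drugs[d], dispense_date = start))
      }
      intended[[sid]] <- data.frame(
        subject_id = sid, broad = "non-TRD",
        narrow1 = if (many) "excluded" else "non-TRD",
        narrow2 = if (many) "excluded" else "non-TRD",
        lithium_user = FALSE, stringsAsFactors = FALSE)
    }
    rx[[sid]] <- recs
  }
  prescriptions <- do.call(rbind, rx)
  rownames(prescriptions) <- NULL
  ect_events <- if (length(ect)) do.call(rbind, ect) else
    data.frame(subject_id = character(), date = integer())
  rownames(ect_events) <- NULL
  intended <- do.call(rbind, intended)
  rownames(intended) <- NULL
  list(prescriptions = prescriptions, ect_events = ect_events,
       intended = intended)
}

#' Simulate a two-population reference panel
#'
#' Reference genotypes at the study variants: `n_target` samples at the study
#' allele frequencies (the target population) and `n_other` samples with
#' frequencies shifted by the configured delta, for exercising the
#' PCA-projection ancestry screen without any external panel.
#'
#' @param config a [sim_config()].
#' @param variants variant table of the study [geno_matrix()].
#' @param freqs generating allele frequencies of the study variants.
#' @param n_target,n_other panel sizes (defaults 200 / 60).
#' @return list with `genotypes` (a [geno_matrix()]) and `populations`
#'   (character labels, `"target"` / `"other"`).
#' @export
simulate_reference <- function(config, variants, freqs, n_target = 200,
                               n_other = 60) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "reference"))
  m <- nrow(variants)
  shift_dir <- sample(c(-1, 1), m, replace = TRUE)
  p2 <- pmin(pmax(freqs + shift_dir * config$ancestry_freq_shift, 0.01), 0.99)
  n <- n_target + n_other
  D <- matrix(0L, n, m)
  for (j in seq_len(m))
    D[, j] <- stats::rbinom(n, 2L, c(rep(freqs[j], n_target),
                                     rep(p2[j], n_other)))
  list(genotypes = geno_matrix(D, variants,
                               sprintf("REF%04d", seq_len(n))),
       populations = rep(c("target", "other"), c(n_target, n_other)))
}

#' Generate a complete synthetic study
#'
#' Runs the genotype, phenotype, treatment-history, and reference-panel
#' generators under one seed and assembles the full study object: subject
#' roster (cohort label, reported sex, X-heterozygosity summary),
#' prescriptions, ECT events, genotypes, per-trait weight tables, the truth
#' table, and a two-population reference panel. Reported sex is flipped in a
#' configured fraction of subjects to exercise the sex-mismatch screen;
#' X-chromosome markers themselves are not simulated — the per-subject
#' X-heterozygosity rate is emitted directly.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_study`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  gen <- simulate_genotypes(config)
  truth <- simulate_phenotypes(gen$genotypes, gen$weights, config,
                               planted = gen$planted)
  hist <- simulate_treatment_history(truth, config)

  set.seed(child_seed(config$seed, "subjects"))
  n <- config$n_subjects
  sex_true <- ifelse(stats::runif(n) < config$female_fraction,
                     "female", "male")
  x_het <- ifelse(sex_true == "female",
                  stats::runif(n, 0.22, 0.35), stats::runif(n, 0, 0.01))
  flip <- stats::runif(n) < config$sex_mismatch_rate
  reported <- ifelse(flip, ifelse(sex_true == "female", "male", "female"),
                     sex_true)
  cohort <- ifelse(
    truth$trd == 1L, names(config$cohort_fractions)[1],
    sample(names(config$cohort_fractions)[2:3], n, replace = TRUE,
           prob = config$cohort_fractions[2:3]))
  subjects <- data.frame(subject_id = truth$subject_id, cohort = cohort,
                         reported_sex = reported, x_het_rate = x_het,
                         ancestry_outlier = gen$ancestry_outlier,
                         stringsAsFactors = FALSE)
  truth$intended_broad <- hist$intended$broad
  truth$intended_narrow1 <- hist$intended$narrow1
  truth$intended_narrow2 <- hist$intended$narrow2
  truth$lithium_user <- hist$intended$lithium_user

  ref <- simulate_reference(config, gen$genotypes$variants, gen$freqs)
  structure(list(config = config, subjects = subjects,
                 prescriptions = hist$prescriptions,
                 ect_events = hist$ect_events,
                 genotypes = gen$genotypes, weights = gen$weights,
                 planted = gen$planted, truth = truth,
                 reference = ref),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic_study: %d subjects (%d TRD), %d variants, ",
                     "%d prescriptions, %d ECT events\n"),
              nrow(x$subjects), sum(x$truth$trd), ncol(x$genotypes$dosages),
              nrow(x$prescriptions), nrow(x$ect_events)))
  invisible(x)
}
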
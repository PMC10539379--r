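#' Configuration of a full pipeline run
#'
#' Bundles the stage parameters of one reproducible run: either a simulation
#' config (the default) or paths to register + genotype inputs, the phenotype
#' rules, QC thresholds, scoring and association settings. Defaults are the
#' study parameterization: gap 120 days, adequacy 42 days, per-variant call
#' rate 0.98 (pre-screen 0.95), HWE p 1e-6, differential call rate 0.01, MAF
#' 0.01, FHET 0.20, pi-hat 0.2, ancestry 6 SD, weight filters MAF 0.1 /
#' INFO 0.9 / MHC chr6:28-34 Mb, K = 0.10, first four PCs.
#'
#' @param simulate generate the inputs with [simulate_study()]? Default TRUE.
#' @param sim a [sim_config()]; its seed governs the run when simulating.
#' @param paths named list of input paths when `simulate = FALSE`:
#'   `genotypes` (PLINK prefix or `.vcf`), `prescriptions`, `ect_events`,
#'   `subjects` (CSVs), `weights` (named character vector of weight-table
#'   paths, must include `lithium` and `antidep`).
#' @param phenotype a [phenotype_params()].
#' @param qc named list of QC thresholds (see [snp_qc()], [sample_qc()],
#'   [relatedness_prune()], [ancestry_outliers()]).
#' @param score_maf,score_info weight-filter thresholds.
#' @param n_pcs number of principal components as covariates (default 4).
#' @param K assumed population TRD proportion among MDD (default 0.10).
#' @param out_dir optional output directory; NULL keeps results in memory.
#' @param seed global seed; stages derive child seeds from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(simulate = TRUE, sim = sim_config(), paths = list(),
                       phenotype = phenotype_params(),
                       qc = list(callrate_prescreen = 0.95, callrate = 0.98,
                                 hwe_p = 1e-6, diff_callrate = 0.01,
                                 maf = 0.01, sample_callrate = 0.98,
                                 fhet = 0.20, pihat = 0.2,
                                 ancestry_sd = 6),
                       score_maf = 0.1, score_info = 0.9,
                       n_pcs = 4, K = 0.10, out_dir = NULL, seed = NULL) {
  if (!simulate) {
    need <- c("genotypes", "prescriptions", "ect_events", "subjects",
              "weights")
    missing_in <- setdiff(need, names(paths))
    if (length(missing_in))
      stop("simulation disabled but input paths missing: ",
           paste(missing_in, collapse = ", "))
  }
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(simulate = simulate, sim = sim, paths = paths,
                 phenotype = phenotype, qc = qc, score_maf = score_maf,
                 score_info = score_info, n_pcs = n_pcs, K = K,
                 out_dir = out_dir, seed = sim$seed),
            class = "run_config")
}

# first `k` PCs of the standardized dosage matrix (missing calls mean-imputed)
compute_pcs <- function(G, k = 4) {
  D <- G$dosages
  p <- colMeans(D, na.rm = TRUE) / 2
  sdv <- sqrt(2 * p * (1 - p))
  ok <- is.finite(sdv) & sdv > 0
  M <- sweep(D[, ok, drop = FALSE], 2, 2 * p[ok], "-")
  M <- sweep(M, 2, sdv[ok], "/")
  M[is.na(M)] <- 0
  sv <- svd(M, nu = k, nv = 0)
  pcs <- sv$u %*% diag(sv$d[seq_len(k)], k)
  out <- data.frame(subject_id = G$subject_ids, pcs,
                    stringsAsFactors = FALSE)
  names(out)[-1] <- paste0("PC", seq_len(k))
  out
}

#' Run the full pipeline: simulate/load, classify, QC, score, associate
#'
#' Executes the stages in register order — input assembly, TRD/non-TRD
#' classification, variant QC, sample QC (call rate, heterozygosity, sex),
#' relatedness pruning, ancestry screen, principal components, weight
#' filtering and polygenic scoring per trait, then the association battery —
#' and collects every intermediate plus a provenance record (config echo,
#' seed, per-stage counts) sufficient to re-run bit-identically. With
#' `out_dir` set, intermediates are also written to disk (CSV/TSV/JSON).
#'
#' @param config a [run_config()].
#' @return object of class `trd_run`: list with `classifications`,
#'   `qc_reports`, `pcs`, `scores`, `battery`, `provenance`, and (when
#'   simulated) `study`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  prov <- list(seed = config$seed, stages = list())
  note <- function(stage, ...) prov$stages[[stage]] <<- list(...)

  if (config$simulate) {
    study <- simulate_study(config$sim)
    subjects <- study$subjects
    prescriptions <- study$prescriptions
    ect_events <- study$ect_events
    G <- study$genotypes
    weights <- study$weights
    reference <- study$reference
  } else {
    p <- config$paths
    study <- NULL
    subjects <- utils::read.csv(p$subjects, stringsAsFactors = FALSE)
    prescriptions <- utils::read.csv(p$prescriptions,
                                     stringsAsFactors = FALSE)
    ect_events <- utils::read.csv(p$ect_events, stringsAsFactors = FALSE)
    G <- if (grepl("\\.vcf(\\.gz)?$", p$genotypes)) read_vcf(p$genotypes)
         else read_plink(p$genotypes)
    weights <- lapply(p$weights, read_weight_table)
    reference <- NULL
  }
  note("input", n_subjects = nrow(subjects),
       n_prescriptions = nrow(prescriptions), n_ect = nrow(ect_events),
       n_variants = ncol(G$dosages))

  cls <- classify_subjects(subjects$subject_id, prescriptions, ect_events,
                           config$phenotype)
  note("classify", n_trd_broad = sum(cls$label_broad == "TRD"),
       n_trd_narrow1 = sum(cls$label_narrow1 == "TRD"),
       n_trd_narrow2 = sum(cls$label_narrow2 == "TRD"))

  reports <- list()
  status <- cls$label_broad[match(G$subject_ids, cls$subject_id)] == "TRD"
  sqc <- snp_qc(G, status,
                callrate_prescreen = config$qc$callrate_prescreen,
                callrate = config$qc$callrate, hwe_p = config$qc$hwe_p,
                diff_callrate = config$qc$diff_callrate,
                maf = config$qc$maf)
  G <- sqc$genotypes; reports$snp_qc <- sqc$report

  idx <- match(G$subject_ids, subjects$subject_id)
  smp <- sample_qc(G, subjects$reported_sex[idx], subjects$x_het_rate[idx],
                   callrate = config$qc$sample_callrate,
                   fhet = config$qc$fhet)
  G <- smp$genotypes; reports$sample_qc <- smp$report

  rel <- relatedness_prune(G, pihat_threshold = config$qc$pihat)
  G <- rel$genotypes; reports$relatedness <- rel$report

  if (!is.null(reference)) {
    anc <- ancestry_outliers(G, reference$genotypes, reference$populations,
                             target_population = "target",
                             sd_threshold = config$qc$ancestry_sd)
    G <- anc$genotypes; reports$ancestry <- anc$report
  }
  note("qc", n_samples = nrow(G$dosages), n_variants = ncol(G$dosages))

  pcs <- compute_pcs(G, k = config$n_pcs)

  scores <- list()
  for (tr in names(weights)) {
    fw <- filter_weights(weights[[tr]], G, maf = config$score_maf,
                         info = config$score_info)
    reports[[paste0("weights_", tr)]] <- fw$report
    scores[[tr]] <- prs_score(G, fw$weights, trait = tr)
  }
  note("score", traits = names(scores),
       n_scored = nrow(scores[[1]]))

  cls_qc <- cls[cls$subject_id %in% G$subject_ids, , drop = FALSE]
  battery <- run_battery(cls_qc, scores, pcs, n_pcs = config$n_pcs,
                         K = config$K)
  note("assoc", n_primary = nrow(battery$primary))

  run <- structure(list(classifications = cls_qc, qc_reports = reports,
                        pcs = pcs, scores = scores, battery = battery,
                        provenance = prov, config = config, study = study),
                   class = "trd_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$classifications,
                   file.path(dir, "classifications.csv"), row.names = FALSE)
  utils::write.csv(run$pcs, file.path(dir, "pcs.csv"), row.names = FALSE)
  for (tr in names(run$scores))
    utils::write.csv(run$scores[[tr]],
                     file.path(dir, sprintf("scores_%s.csv", tr)),
                     row.names = FALSE)
  utils::write.csv(as.data.frame(run$battery),
                   file.path(dir, "battery.csv"), row.names = FALSE)
  utils::write.csv(run$battery$quartiles,
                   file.path(dir, "quartiles.csv"), row.names = FALSE)
  for (nm in names(run$qc_reports))
    write_qc_report(run$qc_reports[[nm]],
                    file.path(dir, sprintf("qc_%s.json", nm)))
  cfg <- run$config
  jsonlite::write_json(
    list(seed = run$provenance$seed, stages = run$provenance$stages,
         params = list(simulate = cfg$simulate, qc = cfg$qc,
                       score_maf = cfg$score_maf, score_info = cfg$score_info,
                       n_pcs = cfg$n_pcs, K = cfg$K,
                       gap_days = cfg$phenotype$gap_days,
                       min_days = cfg$phenotype$min_days)),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.trd_run <- function(x, ...) {
  s <- x$provenance$stages
  cat("trd_run (seed", x$provenance$seed, ")\n")
  cat(sprintf("  input:    %d subjects, %d variants, %d prescriptions\n",
              s$input$n_subjects, s$input$n_variants,
              s$input$n_prescriptions))
  cat(sprintf("  classify: TRD broad/narrow_1/narrow_2 = %d/%d/%d\n",
              s$classify$n_trd_broad, s$classify$n_trd_narrow1,
              s$classify$n_trd_narrow2))
  cat(sprintf("  post-QC:  %d samples, %d variants\n",
              s$qc$n_samples, s$qc$n_variants))
  cat("\n")
  print(x$battery)
  invisible(x)
}
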
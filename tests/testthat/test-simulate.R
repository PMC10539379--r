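# a small config for fast tests; study-condition knobs stay at their defaults
small_cfg <- function(seed = 11, ...) {
  sim_config(n_subjects = 300, n_snps = 300, seed = seed, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(cohort_fractions = c(0.5, 0.4, 0.2)))
  expect_error(sim_config(maf_range = c(0, 0.5)))
  expect_error(sim_config(or_per_sd_lithium = -1))
  expect_error(sim_config(base_trd_rate = 1.2))
  expect_error(sim_config(n_snps = 20, n_planted_per_filter = 12),
               "invalid")
  expect_error(sim_config(adequate_days = 5000), "longest generatable")
})

test_that("simulated genotypes respect bounds, frequency, and determinism", {
  cfg <- small_cfg(missing_rate = 0)
  gen <- simulate_genotypes(cfg)
  expect_false(anyNA(gen$genotypes$dosages))
  expect_true(all(gen$genotypes$dosages %in% 0:2))

  # same seed, bit-identical; different seed differs
  gen2 <- simulate_genotypes(cfg)
  expect_identical(gen$genotypes$dosages, gen2$genotypes$dosages)
  expect_identical(gen$weights, gen2$weights)
  gen3 <- simulate_genotypes(small_cfg(missing_rate = 0, seed = 12))
  expect_false(identical(gen$genotypes$dosages, gen3$genotypes$dosages))

  # empirical allele frequency tracks the generating frequency
  cfg5 <- sim_config(n_subjects = 5000, n_snps = 60,
                     maf_range = c(0.3, 0.3), missing_rate = 0,
                     ancestry_outlier_rate = 0, seed = 2)
  g5 <- simulate_genotypes(cfg5)
  emp <- colMeans(g5$genotypes$dosages) / 2
  expect_true(all(abs(emp - 0.3) < 0.02))

  # missingness is injected at the requested rate
  gm <- simulate_genotypes(small_cfg(missing_rate = 0.05))
  expect_equal(mean(is.na(gm$genotypes$dosages)), 0.05, tolerance = 0.01)
})

test_that("planted weight-table violations are exactly what the filters catch", {
  # frequencies above 0.15 so no *natural* MAF-filter violations arise and
  # the planted rows are the only removable ones
  cfg <- small_cfg(missing_rate = 0, maf_range = c(0.15, 0.5))
  gen <- simulate_genotypes(cfg)
  res <- filter_weights(gen$weights$lithium, gen$genotypes)
  caught <- setdiff(gen$weights$lithium$id, res$weights$id)
  expect_setequal(caught, gen$planted$id)
  rb <- res$report$removed_by
  k <- cfg$n_planted_per_filter
  expect_equal(rb[["info"]], k)
  expect_equal(rb[["strand_ambiguous"]], k)
  expect_equal(rb[["mhc"]], k)
  expect_equal(rb[["duplicate_id"]], 2L * k)  # original + copy
})

test_that("null effects give case rates at the base rate; degenerate rates degenerate", {
  cfg <- sim_config(n_subjects = 6000, n_snps = 120, seed = 5,
                    or_per_sd_lithium = 1, or_per_sd_antidep = 1,
                    base_trd_rate = 0.3)
  gen <- simulate_genotypes(cfg)
  truth <- simulate_phenotypes(gen$genotypes, gen$weights, cfg, gen$planted)
  expect_lt(abs(mean(truth$trd) - 0.3), 0.02)
  # true scores are standardized within the sample
  expect_equal(mean(truth$z_lithium), 0, tolerance = 1e-8)
  expect_equal(sd(truth$z_lithium), 1, tolerance = 1e-8)

  cfg0 <- small_cfg(base_trd_rate = 0)
  gen0 <- simulate_genotypes(cfg0)
  t0 <- simulate_phenotypes(gen0$genotypes, gen0$weights, cfg0, gen0$planted)
  expect_true(all(t0$trd == 0))
})

test_that("logistic refit on the truth table recovers the generating log-OR", {
  cfg <- sim_config(n_subjects = 50000, n_snps = 200, seed = 9,
                    missing_rate = 0, ancestry_outlier_rate = 0)
  gen <- simulate_genotypes(cfg)
  truth <- simulate_phenotypes(gen$genotypes, gen$weights, cfg, gen$planted)
  fit <- glm(trd ~ z_lithium + z_antidep, data = truth, family = binomial())
  expect_equal(unname(coef(fit)["z_lithium"]), log(1.12), tolerance = 0.03)
  expect_equal(unname(coef(fit)["z_antidep"]), log(0.98), tolerance = 0.03)
})

test_that("treatment histories realize the intended phenotype labels", {
  cfg <- small_cfg()
  gen <- simulate_genotypes(cfg)
  truth <- simulate_phenotypes(gen$genotypes, gen$weights, cfg, gen$planted)
  hist <- simulate_treatment_history(truth, cfg)

  # every prescribed/ECT subject is on the roster
  expect_true(all(hist$prescriptions$subject_id %in% truth$subject_id))
  expect_true(all(hist$ect_events$subject_id %in% truth$subject_id))
  # ECT exactly for the TRD subjects
  expect_setequal(hist$ect_events$subject_id,
                  truth$subject_id[truth$trd == 1])

  # classification round-trip matches the generator's intent exactly
  cls <- classify_subjects(truth$subject_id, hist$prescriptions,
                           hist$ect_events,
                           phenotype_params(gap_days = cfg$gap_days,
                                            min_days = cfg$adequate_days))
  expect_equal(cls$label_broad, hist$intended$broad)
  expect_equal(cls$label_narrow1, hist$intended$narrow1)
  expect_equal(cls$label_narrow2, hist$intended$narrow2)
  expect_equal(cls$lithium_user, hist$intended$lithium_user)
})

test_that("a noise-free profile makes every ECT subject narrow_2 TRD", {
  cfg <- small_cfg(ect_profile = c(none = 0, inadequate = 0,
                                   one_adequate = 0, two_plus_adequate = 1),
                   nonect_many_adequate_rate = 0)
  gen <- simulate_genotypes(cfg)
  truth <- simulate_phenotypes(gen$genotypes, gen$weights, cfg, gen$planted)
  hist <- simulate_treatment_history(truth, cfg)
  cls <- classify_subjects(truth$subject_id, hist$prescriptions,
                           hist$ect_events)
  ect_ids <- unique(hist$ect_events$subject_id)
  expect_true(all(cls$label_narrow2[cls$subject_id %in% ect_ids] == "TRD"))
  # and nobody is excluded anywhere
  expect_false(any(cls$label_narrow1 == "excluded"))
})

test_that("lithium fraction zero removes all lithium records", {
  cfg <- small_cfg(lithium_fraction = 0)
  gen <- simulate_genotypes(cfg)
  truth <- simulate_phenotypes(gen$genotypes, gen$weights, cfg, gen$planted)
  hist <- simulate_treatment_history(truth, cfg)
  expect_false(any(hist$prescriptions$atc_code == "N05AN01"))
})

test_that("full study assembly is deterministic and internally consistent", {
  study <- simulate_study(small_cfg())
  study2 <- simulate_study(small_cfg())
  expect_identical(study$prescriptions, study2$prescriptions)
  expect_identical(study$truth, study2$truth)
  other <- simulate_study(small_cfg(seed = 99))
  expect_false(identical(study$prescriptions$dispense_date,
                         other$prescriptions$dispense_date))

  expect_equal(nrow(study$truth), 300)
  expect_setequal(study$subjects$subject_id, study$truth$subject_id)
  # TRD subjects sit in the ECT-referral cohort
  expect_true(all(study$subjects$cohort[study$truth$trd == 1] == "ect"))
  # reference panel shares the variant set
  expect_equal(study$reference$genotypes$variants$id,
               study$genotypes$variants$id)
})
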
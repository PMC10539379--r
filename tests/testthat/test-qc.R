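# small genotype fixture generator: n subjects, frequencies p, no structure
gen_geno <- function(n, p, seed = 1, ids = sprintf("rs%04d", seq_along(p))) {
  set.seed(seed)
  m <- length(p)
  D <- vapply(p, function(pp) rbinom(n, 2, pp), integer(n))
  geno_matrix(D, data.frame(id = ids, chr = "1",
                            pos = seq_len(m) * 1000,
                            allele1 = "A", allele2 = "G"))
}

test_that("HWE exact test agrees with full enumeration up to n = 200", {
  set.seed(5)
  for (rep in 1:200) {
    n <- sample(1:200, 1)
    counts <- as.vector(stats::rmultinom(1, n, prob = runif(3, 0.05, 1)))
    expect_equal(hwe_exact_test(counts[1], counts[2], counts[3]),
                 oracle_hwe_p(counts[1], counts[2], counts[3]),
                 tolerance = 1e-12)
  }
  # modal configuration at allele frequency 0.5
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-3)
  # monomorphic
  expect_equal(hwe_exact_test(50, 0, 0), 1)
  # maximal heterozygote deficit
  expect_lt(hwe_exact_test(10, 0, 10), 1e-5)
  # all-heterozygote configuration is wildly disequilibrated at n = 100
  expect_lt(hwe_exact_test(0, 100, 0), 1e-6)
})

test_that("snp_qc removes variants for the reasons it reports", {
  G <- gen_geno(200, rep(0.3, 30), seed = 2)
  D <- G$dosages
  D[, 1] <- 0L                                   # invariant
  D[1:7, 2] <- NA_integer_                       # call rate 0.965 < 0.98
  D[, 3] <- rep(1L, 200)                         # all-het: HWE failure
  D[sample(200, 2), 4] <- NA_integer_            # call rate 0.99: retained
  D[, 5] <- rbinom(200, 2, 0.005)                # MAF < 0.01
  status <- rep(c(TRUE, FALSE), each = 100)
  D[1:50, 6] <- NA_integer_                      # differential call rate 0.5
  G2 <- geno_matrix(D, G$variants)
  res <- snp_qc(G2, status)
  gone <- setdiff(G$variants$id, res$report$retained)
  expect_setequal(gone, G$variants$id[c(1, 2, 3, 5, 6)])
  expect_equal(res$report$n_input - res$report$n_removed,
               length(res$report$retained))
  expect_true(res$report$removed_by[["hwe"]] >= 1)
  expect_true(res$report$removed_by[["invariant"]] >= 1)

  # idempotence: re-running on the filtered output removes nothing
  res2 <- snp_qc(res$genotypes, status)
  expect_equal(ncol(res2$genotypes$dosages), ncol(res$genotypes$dosages))
})

test_that("HWE screening within strata keeps stratified-but-balanced variants", {
  # a variant in HWE within cases and controls separately at different
  # frequencies must survive, even though the pooled sample is disequilibrated
  set.seed(9)
  n <- 400
  status <- rep(c(TRUE, FALSE), each = n / 2)
  p <- ifelse(status, 0.1, 0.6)
  D <- cbind(vapply(p, function(pp) rbinom(1, 2, pp), integer(1)),
             rbinom(n, 2, 0.4))
  G <- geno_matrix(D, data.frame(id = c("strat", "plain"), chr = "1",
                                 pos = c(1, 2), allele1 = "A",
                                 allele2 = "G"))
  res <- snp_qc(G, status)
  expect_true("strat" %in% res$report$retained)
})

test_that("sample_qc flags call rate, heterozygosity excess, and sex mismatch", {
  set.seed(4)
  p <- runif(5000, 0.1, 0.5)
  G <- gen_geno(60, p, seed = 4)
  D <- G$dosages
  D[1, sample(5000, 150)] <- NA_integer_    # sample 1: call rate 0.97
  D[2, ] <- ifelse(D[2, ] == 1L, 2L, D[2, ])  # sample 2: no hets, F ~ 1
  G2 <- geno_matrix(D, G$variants)
  sex <- rep("female", 60)
  xhet <- runif(60, 0.25, 0.35)
  xhet[3] <- 0                                 # sample 3: male pattern
  xhet[4] <- 0.1                               # ambiguous: never removed
  res <- sample_qc(G2, sex, xhet)
  removed <- setdiff(G$subject_ids, res$report$retained)
  expect_setequal(removed, G$subject_ids[1:3])
  det <- res$report$details
  expect_gt(det$fhet[2], 0.2)
  # well-behaved samples sit near F = 0
  expect_lt(max(abs(det$fhet[5:60])), 0.05)
  # idempotence
  keep <- match(res$report$retained, G$subject_ids)
  res2 <- sample_qc(res$genotypes, sex[keep], xhet[keep])
  expect_equal(res2$report$n_removed, 0L)
})

test_that("pi-hat recovers duplicates, parent-offspring, and unrelated pairs", {
  m <- 5000
  reps <- 50
  est <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    set.seed(100 + r)
    # common variants, as in a pruned IBD panel
    p <- runif(m, 0.2, 0.5)
    parent <- rbinom(m, 2, p)
    other <- rbinom(m, 2, p)
    third <- rbinom(m, 2, p)
    # child: one allele transmitted from the parent, one from the population
    transmitted <- rbinom(m, 1, parent / 2)
    child <- transmitted + rbinom(m, 1, p)
    D <- rbind(parent, parent, child, other, third)
    G <- geno_matrix(D, data.frame(id = sprintf("v%04d", 1:m), chr = "1",
                                   pos = 1:m, allele1 = "A", allele2 = "G"),
                     c("dup1", "dup2", "child", "other", "third"))
    # frequencies from a large external sample, as in pipeline use
    PH <- pihat_matrix(G, freqs = p)
    est[r, ] <- c(PH["dup1", "dup2"], PH["dup1", "child"],
                  PH["other", "third"])
  }
  expect_true(all(abs(est[, 1] - 1.0) < 0.05))
  expect_true(all(abs(est[, 2] - 0.5) < 0.05))
  expect_true(all(abs(est[, 3] - 0.0) < 0.05))
})

test_that("relatedness pruning removes one member per flagged pair", {
  set.seed(12)
  p <- runif(1500, 0.1, 0.5)
  base <- vapply(p, function(pp) rbinom(4, 2, pp), integer(4))
  D <- rbind(base, base[1, ])               # subject 5 duplicates subject 1
  D[5, sample(1500, 30)] <- NA_integer_     # lower call rate -> dropped
  G <- geno_matrix(D, data.frame(id = sprintf("v%04d", 1:1500), chr = "1",
                                 pos = 1:1500, allele1 = "A",
                                 allele2 = "G"),
                   paste0("s", 1:5))
  res <- relatedness_prune(G)
  expect_equal(res$pihat$id1, "s1")
  expect_equal(res$pihat$id2, "s5")
  expect_gt(res$pihat$pihat, 0.9)
  expect_setequal(res$report$retained, c("s1", "s2", "s3", "s4"))
})

test_that("ancestry screen flags the shifted population and spares the target", {
  set.seed(21)
  m <- 2000
  p <- runif(m, 0.2, 0.5)
  shift <- pmin(pmax(p + sample(c(-1, 1), m, TRUE) * 0.2, 0.01), 0.99)
  draw <- function(n, pr) t(vapply(seq_len(n), function(i)
    rbinom(m, 2, pr), integer(m)))
  v <- data.frame(id = sprintf("v%04d", 1:m), chr = "1", pos = 1:m,
                  allele1 = "A", allele2 = "G")
  ref <- geno_matrix(rbind(draw(150, p), draw(50, shift)), v,
                     sprintf("R%03d", 1:200))
  pops <- rep(c("target", "other"), c(150, 50))
  study <- geno_matrix(rbind(draw(40, p), draw(40, shift)), v,
                       sprintf("S%03d", 1:80))
  res <- ancestry_outliers(study, ref, pops, target_population = "target")
  flagged <- res$projection$flagged
  expect_equal(sum(flagged[1:40]), 0)          # target-drawn: none flagged
  expect_gte(mean(flagged[41:80]), 0.9)        # shifted: nearly all flagged
  # an infinite threshold flags nobody
  res_inf <- ancestry_outliers(study, ref, pops,
                               target_population = "target",
                               sd_threshold = Inf)
  expect_equal(sum(res_inf$projection$flagged), 0)
})
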
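# Independent oracles, deliberately implemented by different routes than the
# package code they check.

# Brute force over all date-ordered contiguous partitions of one drug's
# dispense dates: the unique partition whose within-block gaps are all
# <= gap_days and whose between-block gaps are all > gap_days.
oracle_episode_partition <- function(dates, gap_days) {
  dates <- sort(dates)
  k <- length(dates)
  if (k == 1) return(list(dates))
  best <- NULL
  for (mask in 0:(2^(k - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(seq_len(k - 1) - 1)) > 0)
    blocks <- split(dates, cumsum(c(1, seq_len(k - 1) %in% cuts)))
    ok_within <- all(vapply(blocks, function(b)
      length(b) == 1 || all(diff(b) <= gap_days), logical(1)))
    ends <- vapply(blocks, max, numeric(1))
    starts <- vapply(blocks, min, numeric(1))
    ok_between <- length(blocks) == 1 ||
      all(starts[-1] - ends[-length(ends)] > gap_days)
    if (ok_within && ok_between) {
      if (!is.null(best)) stop("partition not unique")
      best <- unname(blocks)
    }
  }
  if (is.null(best)) stop("no valid partition")
  best
}

# Levene/Haldane exact HWE distribution computed from the closed-form
# absolute probabilities (not the normalized-vector route the package uses).
oracle_hwe_p <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  na <- 2 * n_hom1 + n_het
  nb <- 2 * n_hom2 + n_het
  if (na == 0 || nb == 0) return(1)
  prob_h <- function(h) {
    n1 <- (na - h) / 2; n2 <- (nb - h) / 2
    exp(lfactorial(n) - lfactorial(n1) - lfactorial(h) - lfactorial(n2) +
          h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n))
  }
  hs <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  ps <- vapply(hs, prob_h, numeric(1))
  obs <- prob_h(n_het)
  sum(ps[ps <= obs * (1 + 1e-12)])
}

# Textbook Cochran-Armitage trend statistic for a 2 x k table with scores s.
oracle_ca_statistic <- function(cases, totals, s = seq_along(cases)) {
  N <- sum(totals)
  pbar <- sum(cases) / N
  num <- sum(s * (cases - totals * pbar))
  den <- pbar * (1 - pbar) * (sum(totals * s^2) - sum(totals * s)^2 / N)
  num^2 / den
}

# Manual Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m / i * p[o[i]])
    adj[o[i]] <- prev
  }
  adj
}

# Small deterministic register fixture: one subject per scenario.
fixture_prescriptions <- function() {
  rbind(
    data.frame(subject_id = "full_trd", atc_code = "N06AB04",
               dispense_date = c(0, 30, 60, 90)),
    data.frame(subject_id = "full_trd", atc_code = "N06AX11",
               dispense_date = c(100, 150, 200)),
    data.frame(subject_id = "full_trd", atc_code = "N05AN01",
               dispense_date = c(310, 340)),
    data.frame(subject_id = "one_drug", atc_code = "N06AB06",
               dispense_date = c(10, 40, 80)),
    data.frame(subject_id = "inadequate", atc_code = "N06AB04",
               dispense_date = c(50, 70)),                 # 20-day span
    data.frame(subject_id = "broken_chain", atc_code = "N06AB04",
               dispense_date = c(0, 200, 230)),            # gap 200 > 120
    data.frame(subject_id = "many_adequate", atc_code = "N06AB03",
               dispense_date = c(0, 60)),
    data.frame(subject_id = "many_adequate", atc_code = "N06AB04",
               dispense_date = c(100, 160)),
    data.frame(subject_id = "many_adequate", atc_code = "N06AX16",
               dispense_date = c(300, 370)),
    data.frame(subject_id = "mild_control", atc_code = "N06AB04",
               dispense_date = c(0, 30, 60)))
}

fixture_ect <- function() {
  data.frame(subject_id = c("full_trd", "one_drug", "inadequate",
                            "broken_chain"),
             date = c(300, 300, 300, 300))
}

fixture_roster <- function() {
  c("full_trd", "one_drug", "inadequate", "broken_chain", "many_adequate",
    "mild_control", "no_records")
}
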
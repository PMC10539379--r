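test_that("singleton and boundary gap cases follow the inclusive 120-day rule", {
  one <- build_episodes(data.frame(subject_id = "s", atc_code = "N06AB04",
                                   dispense_date = 0))
  expect_equal(nrow(one), 1L)
  expect_equal(one$duration_days, 0L)
  expect_equal(one$n_dispenses, 1L)

  # gap of exactly 120 stays within one episode
  ex <- build_episodes(data.frame(subject_id = "s", atc_code = "N06AB04",
                                  dispense_date = c(0, 120)))
  expect_equal(nrow(ex), 1L)
  expect_equal(ex$duration_days, 120L)

  # 130-day gap splits
  sp <- build_episodes(data.frame(subject_id = "s", atc_code = "N06AB04",
                                  dispense_date = c(0, 50, 180)))
  expect_equal(nrow(sp), 2L)
  expect_equal(sp$duration_days, c(50L, 0L))
  expect_equal(sp$start_date, c(0L, 180L))
})

test_that("episode construction matches the brute-force partition oracle", {
  set.seed(42)
  for (rep in 1:40) {
    k <- sample(1:10, 1)
    dates <- sort(sample(0:800, k))
    gap <- sample(c(30, 120, 200), 1)
    ep <- build_episodes(data.frame(subject_id = "s", atc_code = "N06AB04",
                                    dispense_date = dates), gap_days = gap)
    oracle <- oracle_episode_partition(dates, gap)
    expect_equal(nrow(ep), length(oracle))
    expect_equal(ep$start_date, vapply(oracle, min, numeric(1)))
    expect_equal(ep$end_date, vapply(oracle, max, numeric(1)))
    expect_equal(ep$n_dispenses, lengths(oracle))
  }
})

test_that("episodes partition the records and respect record-order invariance", {
  set.seed(7)
  recs <- data.frame(
    subject_id = sample(c("a", "b"), 40, replace = TRUE),
    atc_code = sample(c("N06AB04", "N06AX11"), 40, replace = TRUE),
    dispense_date = sample(0:1000, 40))
  ep <- build_episodes(recs)
  # partition: dispenses per (subject, drug) are covered exactly once
  uniq <- unique(recs)
  expect_equal(sum(ep$n_dispenses), nrow(uniq))
  agg <- aggregate(n_dispenses ~ subject_id + atc_code, ep, sum)
  cnt <- aggregate(dispense_date ~ subject_id + atc_code, uniq, length)
  mg <- merge(agg, cnt)
  expect_equal(mg$n_dispenses, mg$dispense_date)
  # shuffling and duplicating records changes nothing
  shuf <- recs[sample(nrow(recs)), ]
  expect_equal(build_episodes(rbind(shuf, recs[1:5, ])), ep)
})

test_that("gap and adequacy parameters act monotonically", {
  set.seed(11)
  dates <- sort(sample(0:900, 12))
  recs <- data.frame(subject_id = "s", atc_code = "N06AB04",
                     dispense_date = dates)
  n_ep <- vapply(c(30, 60, 120, 250, 1000), function(g)
    nrow(build_episodes(recs, gap_days = g)), numeric(1))
  expect_true(all(diff(n_ep) <= 0))
  ep <- build_episodes(recs)
  n_ad <- vapply(c(0, 20, 42, 100, 500), function(md)
    nrow(adequate_episodes(ep, min_days = md)), numeric(1))
  expect_true(all(diff(n_ad) <= 0))
})

test_that("adequacy boundary is inclusive at 42 days", {
  ep <- data.frame(subject_id = "s", atc_code = "N06AB04", start_date = 0,
                   end_date = c(42, 41, 0, 50, 120),
                   n_dispenses = 2, duration_days = c(42, 41, 0, 50, 120))
  kept <- adequate_episodes(ep)
  expect_equal(kept$duration_days, c(42, 50, 120))
})

test_that("distinct adequate drugs before a cutoff are counted correctly", {
  recs <- rbind(
    data.frame(subject_id = "s", atc_code = "N06AB04",
               dispense_date = c(0, 50)),
    data.frame(subject_id = "s", atc_code = "N06AX11",
               dispense_date = c(10, 60)),
    data.frame(subject_id = "s", atc_code = "N05AN01",    # lithium: not N06A
               dispense_date = c(0, 90)))
  expect_equal(count_distinct_adequate_before(recs, 100), 2L)
  # three adequate episodes of one drug still count once
  multi <- data.frame(subject_id = "s", atc_code = "N06AB04",
                      dispense_date = c(0, 50, 300, 350, 600, 660))
  expect_equal(count_distinct_adequate_before(multi, 1000), 1L)
  # records on/after the cutoff never contribute
  expect_equal(count_distinct_adequate_before(recs, 0), 0L)
  # dispense on the cutoff day itself is excluded ("before", strictly)
  expect_equal(count_distinct_adequate_before(
    data.frame(subject_id = "s", atc_code = "N06AB04",
               dispense_date = c(0, 42)), 42), 0L)
  # truncation at the cutoff re-evaluates adequacy on the remaining chain
  span <- data.frame(subject_id = "s", atc_code = "N06AB04",
                     dispense_date = c(0, 30, 90))
  expect_equal(count_distinct_adequate_before(span, 40), 0L)
  expect_equal(count_distinct_adequate_before(span, 91), 1L)
})

test_that("degenerate inputs are handled explicitly", {
  expect_equal(nrow(build_episodes(NULL)), 0L)
  expect_equal(nrow(build_episodes(empty <- data.frame(
    subject_id = character(), atc_code = character(),
    dispense_date = integer()))), 0L)
  expect_error(build_episodes(data.frame(subject_id = "s", atc_code = "",
                                         dispense_date = 1)), "ATC")
  expect_error(build_episodes(data.frame(subject_id = "s", atc_code = "X",
                                         dispense_date = NA)), "finite")
})
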
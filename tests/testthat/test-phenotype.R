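cls_fixture <- function(...) {
  classify_subjects(fixture_roster(), fixture_prescriptions(), fixture_ect(),
                    phenotype_params(...))
}

test_that("classification applies the broad and narrow rules per subject", {
  cls <- cls_fixture()
  row <- function(id) cls[cls$subject_id == id, ]

  # two adequate antidepressants before ECT at day 300: TRD everywhere
  ft <- row("full_trd")
  expect_equal(ft$label_broad, "TRD")
  expect_equal(ft$label_narrow1, "TRD")
  expect_equal(ft$label_narrow2, "TRD")
  expect_equal(ft$n_adequate_antidep_before_ect, 2L)
  expect_true(ft$lithium_user)

  # one adequate drug: TRD broad/narrow_1, excluded narrow_2
  od <- row("one_drug")
  expect_equal(unlist(od[c("label_broad", "label_narrow1", "label_narrow2")],
                      use.names = FALSE), c("TRD", "TRD", "excluded"))

  # ECT but only a 20-day episode: excluded from both narrow comparisons
  inad <- row("inadequate")
  expect_equal(unlist(inad[c("label_broad", "label_narrow1",
                             "label_narrow2")], use.names = FALSE),
               c("TRD", "excluded", "excluded"))

  # chain broken by a 200-day gap before ECT: both fragments inadequate
  bc <- row("broken_chain")
  expect_equal(bc$n_adequate_antidep_before_ect, 0L)
  expect_equal(bc$label_narrow1, "excluded")

  # no ECT, three adequate drugs: broad control, excluded from narrow
  ma <- row("many_adequate")
  expect_equal(unlist(ma[c("label_broad", "label_narrow1", "label_narrow2")],
                      use.names = FALSE),
               c("non-TRD", "excluded", "excluded"))
  expect_equal(ma$n_adequate_antidep_total, 3L)

  # no records at all: broad control; narrow control requires a record
  nr <- row("no_records")
  expect_equal(nr$label_broad, "non-TRD")
  expect_equal(nr$label_narrow1, "excluded")
  expect_true(is.na(nr$first_ect_date))
})

test_that("narrow labels nest within broad on arbitrary generated registers", {
  set.seed(3)
  for (rep in 1:10) {
    n <- 60
    ids <- sprintf("p%02d", 1:n)
    rx <- data.frame(
      subject_id = sample(ids, 300, replace = TRUE),
      atc_code = sample(c("N06AB04", "N06AX11", "N06AA09", "N05AN01"),
                        300, replace = TRUE),
      dispense_date = sample(0:1000, 300, replace = TRUE))
    ect <- data.frame(subject_id = sample(ids, 15),
                      date = sample(100:900, 15))
    cls <- classify_subjects(ids, rx, ect)
    trd_n <- function(lab) sum(lab == "TRD")
    expect_true(trd_n(cls$label_broad) >= trd_n(cls$label_narrow1))
    expect_true(trd_n(cls$label_narrow1) >= trd_n(cls$label_narrow2))
    # narrow TRD implies broad TRD subject-by-subject
    expect_true(all(cls$label_broad[cls$label_narrow1 == "TRD"] == "TRD"))
    expect_true(all(cls$label_narrow1[cls$label_narrow2 == "TRD"] == "TRD"))
    # broad controls never carry an ECT date
    expect_true(all(is.na(cls$first_ect_date[cls$label_broad == "non-TRD"])))
    # record order and duplication do not change the labels
    cls2 <- classify_subjects(ids, rx[sample(nrow(rx)), ],
                              ect[sample(nrow(ect)), , drop = FALSE])
    expect_equal(cls2[order(cls2$subject_id), ],
                 cls[order(cls$subject_id), ], ignore_attr = TRUE)
  }
})

test_that("lithium flag honours the configured exposure window", {
  cls_full <- cls_fixture(lithium_window = "full")
  cls_pre <- cls_fixture(lithium_window = "pre_ect")
  # full_trd's lithium records start at day 310, after ECT at day 300
  expect_true(cls_full$lithium_user[cls_full$subject_id == "full_trd"])
  expect_false(cls_pre$lithium_user[cls_pre$subject_id == "full_trd"])
})

test_that("comparison rosters drop exclusions and support lithium sensitivity", {
  cls <- cls_fixture()
  broad <- build_comparison(cls, "broad")
  expect_setequal(broad$cases,
                  c("full_trd", "one_drug", "inadequate", "broken_chain"))
  expect_setequal(broad$controls,
                  c("many_adequate", "mild_control", "no_records"))

  n1 <- build_comparison(cls, "narrow_1")
  expect_setequal(n1$cases, c("full_trd", "one_drug"))
  n2 <- build_comparison(cls, "narrow_2")
  expect_setequal(n2$cases, "full_trd")
  expect_true(length(n2$cases) <= length(n1$cases))

  expect_setequal(n1$controls, "mild_control")
  noli <- build_comparison(cls, "narrow_1", exclude_lithium_users = TRUE)
  expect_setequal(noli$cases, "one_drug")
  expect_setequal(noli$controls, n1$controls)

  # no subject on both sides of any comparison
  for (d in c("broad", "narrow_1", "narrow_2"))
    expect_length(intersect(build_comparison(cls, d)$cases,
                            build_comparison(cls, d)$controls), 0)

  expect_error(build_comparison(cls, "narrow_2",
                                exclude_lithium_users = TRUE),
               "unanalyzable")
})

test_that("records for unknown subjects are rejected", {
  expect_error(
    classify_subjects("a", data.frame(subject_id = "ghost",
                                      atc_code = "N06AB04",
                                      dispense_date = 1),
                      NULL),
    "absent from the roster")
})
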
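#' Parameters for TRD / non-TRD classification
#'
#' Bundles the rules used to classify MDD subjects into treatment-resistant
#' (TRD), non-TRD, or excluded under three nested definitions:
#'
#' * `broad`: any ECT event makes a subject TRD; subjects without ECT are
#'   non-TRD.
#' * `narrow_1`: TRD additionally requires >= 1 distinct antidepressant with an
#'   adequate treatment episode before the first ECT session.
#' * `narrow_2`: as narrow_1 but requiring >= 2 distinct antidepressants.
#'
#' Under the narrow definitions the control group is defined independently:
#' subjects with no ECT ever, at least one antidepressant record, and at most
#' `max_adequate_controls` antidepressants of adequate duration. ECT subjects
#' failing a narrow adequacy criterion are *excluded* from that comparison,
#' never moved to the control side; non-ECT subjects with more than
#' `max_adequate_controls` adequate antidepressants (likely non-responders who
#' never reached ECT) are excluded from the narrow comparisons but remain
#' non-TRD under the broad one.
#'
#' @param gap_days within-episode dispense gap (days), default 120.
#' @param min_days adequate episode duration (days), default 42 (6 weeks).
#' @param atc_antidep ATC prefix identifying antidepressants (default "N06A").
#' @param atc_lithium full ATC code for lithium (default "N05AN01").
#' @param max_adequate_controls maximum number of adequate antidepressants a
#'   narrow-definition control may have (default 2).
#' @param controls_require_antidep must narrow controls have at least one
#'   antidepressant record of any duration? Default TRUE.
#' @param lithium_window `"full"` (any lithium record flags the subject) or
#'   `"pre_ect"` (only records before the first ECT).
#' @return a named list of class `phenotype_params`.
#' @export
phenotype_params <- function(gap_days = 120, min_days = 42,
                             atc_antidep = "N06A", atc_lithium = "N05AN01",
                             max_adequate_controls = 2,
                             controls_require_antidep = TRUE,
                             lithium_window = c("full", "pre_ect")) {
  lithium_window <- match.arg(lithium_window)
  stopifnot(gap_days > 0, min_days >= 0, max_adequate_controls >= 0)
  structure(list(gap_days = gap_days, min_days = min_days,
                 atc_antidep = atc_antidep, atc_lithium = atc_lithium,
                 max_adequate_controls = max_adequate_controls,
                 controls_require_antidep = controls_require_antidep,
                 lithium_window = lithium_window),
            class = "phenotype_params")
}

#' Classify subjects as TRD / non-TRD / excluded
#'
#' Applies the broad, narrow_1, and narrow_2 definitions (see
#' [phenotype_params()]) to every subject in the roster. Classification is a
#' pure function of each subject's prescription and ECT records; record order
#' and duplicated records do not affect the result.
#'
#' @param subject_ids character vector: the subject roster. Subjects with no
#'   records at all are classified from an empty history.
#' @param prescriptions data.frame with `subject_id`, `atc_code`,
#'   `dispense_date`.
#' @param ect_events data.frame with `subject_id`, `date`; zero rows allowed.
#' @param params a [phenotype_params()] object.
#' @return data.frame with one row per subject: `subject_id`,
#'   `first_ect_date` (NA if never treated with ECT),
#'   `n_adequate_antidep_before_ect` (NA if no ECT),
#'   `n_adequate_antidep_total`, `n_antidep_records`, `label_broad`,
#'   `label_narrow1`, `label_narrow2` (each `"TRD"`, `"non-TRD"`, or
#'   `"excluded"`), `lithium_user`, `exclusion_reason`.
#' @export
classify_subjects <- function(subject_ids, prescriptions, ect_events,
                              params = phenotype_params()) {
  stopifnot(inherits(params, "phenotype_params"))
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids))
    stop("duplicated subject ids in roster")
  prescriptions <- validate_prescriptions(prescriptions)
  if (is.null(ect_events) || nrow(ect_events) == 0L)
    ect_events <- data.frame(subject_id = character(), date = integer())
  ect_events$subject_id <- as.character(ect_events$subject_id)
  stray <- setdiff(c(prescriptions$subject_id, ect_events$subject_id),
                   subject_ids)
  if (length(stray))
    stop("records refer to subjects absent from the roster: ",
         paste(utils::head(stray, 5L), collapse = ", "))

  rx_split <- split(seq_len(nrow(prescriptions)), prescriptions$subject_id)
  ect_split <- split(ect_events$date, ect_events$subject_id)

  out <- lapply(subject_ids, function(sid) {
    rx <- prescriptions[rx_split[[sid]], , drop = FALSE]
    if (is.null(rx_split[[sid]])) rx <- empty_prescriptions()
    classify_one(sid, rx, ect_split[[sid]], params)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

classify_one <- function(sid, rx, ect_dates, params) {
  first_ect <- if (length(ect_dates)) as.integer(min(ect_dates)) else NA_integer_
  has_ect <- !is.na(first_ect)

  is_antidep <- startsWith(rx$atc_code, params$atc_antidep)
  n_antidep_records <- sum(is_antidep)
  antidep_rx <- rx[is_antidep, , drop = FALSE]

  n_total <- if (nrow(antidep_rx)) {
    ep <- adequate_episodes(
      build_episodes(antidep_rx, gap_days = params$gap_days),
      min_days = params$min_days)
    length(unique(ep$atc_code))
  } else 0L

  n_before <- if (has_ect) {
    count_distinct_adequate_before(rx, first_ect,
                                   atc_prefix = params$atc_antidep,
                                   gap_days = params$gap_days,
                                   min_days = params$min_days)
  } else NA_integer_

  lith_rx <- rx$atc_code == params$atc_lithium
  if (params$lithium_window == "pre_ect" && has_ect)
    lith_rx <- lith_rx & rx$dispense_date < first_ect
  lithium_user <- any(lith_rx)

  reason <- ""
  if (has_ect) {
    broad <- "TRD"
    narrow1 <- if (n_before >= 1L) "TRD" else "excluded"
    narrow2 <- if (n_before >= 2L) "TRD" else "excluded"
    if (narrow2 == "excluded")
      reason <- sprintf("ECT with %d adequate antidepressants before first ECT",
                        n_before)
  } else {
    broad <- "non-TRD"
    ok_control <- n_total <= params$max_adequate_controls &&
      (!params$controls_require_antidep || n_antidep_records >= 1L)
    narrow1 <- narrow2 <- if (ok_control) "non-TRD" else "excluded"
    if (!ok_control)
      reason <- if (n_total > params$max_adequate_controls)
        sprintf("no ECT but %d adequate antidepressants", n_total)
      else "no antidepressant record"
  }

  data.frame(subject_id = sid, first_ect_date = first_ect,
             n_adequate_antidep_before_ect = n_before,
             n_adequate_antidep_total = n_total,
             n_antidep_records = n_antidep_records,
             label_broad = broad, label_narrow1 = narrow1,
             label_narrow2 = narrow2, lithium_user = lithium_user,
             exclusion_reason = reason, stringsAsFactors = FALSE)
}

#' Build a case/control roster for one TRD definition
#'
#' Selects the TRD cases and non-TRD controls under one definition, dropping
#' excluded subjects. For the lithium-use sensitivity analysis, TRD cases with
#' any lithium record can be removed (controls are kept, mirroring the design
#' of excluding lithium exposure from the case side only).
#'
#' @param classifications data.frame from [classify_subjects()].
#' @param definition one of `"broad"`, `"narrow_1"`, `"narrow_2"`.
#' @param exclude_lithium_users drop lithium-using TRD cases? Default FALSE.
#' @return list with `cases` and `controls` (character vectors of subject ids),
#'   `definition`, and `exclude_lithium_users`.
#' @export
build_comparison <- function(classifications,
                             definition = c("broad", "narrow_1", "narrow_2"),
                             exclude_lithium_users = FALSE) {
  definition <- match.arg(definition)
  if (!nrow(classifications)) stop("empty classification table")
  lab <- switch(definition,
                broad = classifications$label_broad,
                narrow_1 = classifications$label_narrow1,
                narrow_2 = classifications$label_narrow2)
  cases <- classifications$subject_id[lab == "TRD"]
  if (exclude_lithium_users) {
    lith <- classifications$subject_id[classifications$lithium_user]
    cases <- setdiff(cases, lith)
  }
  controls <- classifications$subject_id[lab == "non-TRD"]
  if (!length(cases) || !length(controls))
    stop(sprintf("comparison '%s' has %d cases and %d controls: unanalyzable",
                 definition, length(cases), length(controls)))
  list(cases = cases, controls = controls, definition = definition,
       exclude_lithium_users = exclude_lithium_users)
}
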
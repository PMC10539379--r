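#' Build continuous treatment episodes from dispense records
#'
#' Groups prescription records by subject and ATC code and chains consecutive
#' dispenses of the same drug into treatment episodes. A new episode starts
#' whenever the gap between two consecutive dispenses of the same drug exceeds
#' `gap_days`; a gap of exactly `gap_days` does *not* split (the register rule
#' reads "within 120 days" inclusively). Episode duration is the span from the
#' first to the last dispense date of the episode, in days.
#'
#' Dates are integer day offsets from an arbitrary study epoch; calendar
#' conversion belongs at I/O boundaries. Duplicate (subject, ATC, date)
#' records are collapsed to a single dispense.
#'
#' @param records data.frame with columns `subject_id`, `atc_code`,
#'   `dispense_date` (integer day offsets).
#' @param gap_days maximum within-episode gap between consecutive dispenses of
#'   the same drug, in days (default 120).
#' @return data.frame with one row per episode: `subject_id`, `atc_code`,
#'   `start_date`, `end_date`, `n_dispenses`, `duration_days`.
#' @export
#' @examples
#' rec <- data.frame(subject_id = "s1", atc_code = "N06AB04",
#'                   dispense_date = c(0, 50, 180))
#' build_episodes(rec)  # splits at the 130-day gap
build_episodes <- function(records, gap_days = 120) {
  stopifnot(is.numeric(gap_days), length(gap_days) == 1L, gap_days > 0)
  records <- validate_prescriptions(records)
  if (nrow(records) == 0L) return(empty_episodes())

  # collapse duplicate dispenses of the same drug on the same day
  key <- paste(records$subject_id, records$atc_code, records$dispense_date,
               sep = "\r")
  records <- records[!duplicated(key), , drop = FALSE]

  ord <- order(records$subject_id, records$atc_code, records$dispense_date)
  records <- records[ord, , drop = FALSE]

  grp <- paste(records$subject_id, records$atc_code, sep = "\r")
  new_grp <- c(TRUE, grp[-1L] != grp[-length(grp)])
  gap <- c(0L, diff(records$dispense_date))
  # episode boundary: new (subject, drug) group, or gap strictly > gap_days
  boundary <- new_grp | (gap > gap_days)
  ep_id <- cumsum(boundary)

  start <- tapply(records$dispense_date, ep_id, min)
  end <- tapply(records$dispense_date, ep_id, max)
  n <- tabulate(ep_id)
  first <- which(boundary)
  out <- data.frame(
    subject_id = records$subject_id[first],
    atc_code = records$atc_code[first],
    start_date = as.integer(start),
    end_date = as.integer(end),
    n_dispenses = n,
    duration_days = as.integer(end - start),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Filter episodes for adequate treatment duration
#'
#' Retains episodes spanning at least `min_days` days from first to last
#' dispense. The default of 42 days encodes the "at least 6 consecutive
#' weeks" adequacy rule; the boundary is inclusive (a 42-day episode is
#' adequate).
#'
#' @param episodes data.frame as returned by [build_episodes()].
#' @param min_days minimum episode duration in days (default 42).
#' @return the subset of `episodes` with `duration_days >= min_days`.
#' @export
adequate_episodes <- function(episodes, min_days = 42) {
  stopifnot(is.numeric(min_days), length(min_days) == 1L, min_days >= 0)
  episodes[episodes$duration_days >= min_days, , drop = FALSE]
}

#' Count distinct drugs with an adequate episode before a cutoff date
#'
#' Restricts records to those whose ATC code starts with `atc_prefix` and whose
#' dispense date is strictly before `cutoff_date`, rebuilds episodes on the
#' truncated record set, and counts the number of distinct ATC codes with at
#' least one adequate episode. Distinct drugs, not episodes, are counted, at
#' the full ATC-code level. Episodes spanning the cutoff contribute only their
#' pre-cutoff dispenses: treatment received after the cutoff (here, the first
#' ECT session) cannot justify it.
#'
#' @param records data.frame of prescription records (see [build_episodes()]).
#' @param cutoff_date day offset; only dispenses strictly before it count.
#' @param atc_prefix ATC prefix selecting the drug class (default "N06A",
#'   antidepressants).
#' @param gap_days,min_days episode-construction and adequacy parameters.
#' @return integer count of distinct qualifying ATC codes.
#' @export
count_distinct_adequate_before <- function(records, cutoff_date,
                                           atc_prefix = "N06A",
                                           gap_days = 120, min_days = 42) {
  stopifnot(is.finite(cutoff_date))
  records <- validate_prescriptions(records)
  keep <- startsWith(records$atc_code, atc_prefix) &
    records$dispense_date < cutoff_date
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) return(0L)
  ep <- adequate_episodes(build_episodes(records, gap_days = gap_days),
                          min_days = min_days)
  length(unique(ep$atc_code))
}

validate_prescriptions <- function(records) {
  if (is.null(records) || nrow(records) == 0L) return(empty_prescriptions())
  need <- c("subject_id", "atc_code", "dispense_date")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("prescription records lack columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(!is.finite(records$dispense_date)))
    stop("non-finite dispense_date in prescription records")
  records$atc_code <- toupper(as.character(records$atc_code))
  if (any(!nzchar(records$atc_code)))
    stop("empty ATC code in prescription records")
  records$subject_id <- as.character(records$subject_id)
  records$dispense_date <- as.integer(records$dispense_date)
  records[need]
}

empty_prescriptions <- function() {
  data.frame(subject_id = character(), atc_code = character(),
             dispense_date = integer(), stringsAsFactors = FALSE)
}

empty_episodes <- function() {
  data.frame(subject_id = character(), atc_code = character(),
             start_date = integer(), end_date = integer(),
             n_dispenses = integer(), duration_days = integer(),
             stringsAsFactors = FALSE)
}
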
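# Single-T repeat-number estimator. In the MUC2 downstream repeat DNA no
# adjacent T pairs occur except at rare SNPs, so each maximal run of T is
# one event, a TT doublet collapses to one, and the event count scales
# linearly with the number of repeat units: dividing a T-event difference
# by the calibrated per-repeat rate gives the repeat-number difference
# without arranging a single frameshift.

#' Count single-T events in a TR region
#'
#' Each maximal run of `T` counts as one event regardless of its length
#' (a `TT` usually marks a SNP, not two template T positions); runs of
#' length >= 2 are reported as anomalies.
#'
#' @param dna TR-region DNA (character or XString) over A,C,G,T,N.
#' @return list: `t_events` (integer), `t_letters` (total count of T
#'   letters, for users preferring the letter basis over the event
#'   basis), `multi_run_positions` (0-based start positions of runs with
#'   length >= 2).
#' @examples
#' countTEvents("TATT")  # 2 events, 3 letters, one anomaly
#' @export
countTEvents <- function(dna) {
  dna <- toupper(as.character(dna))
  if (!grepl("^[ACGTN]*$", dna))
    stop("TR region must be DNA over {A,C,G,T,N}")
  if (!nzchar(dna))
    return(list(t_events = 0L, t_letters = 0L,
                multi_run_positions = integer(0)))
  r <- rle(.chars(dna))
  starts <- cumsum(c(0L, r$lengths))[seq_along(r$lengths)]
  tr <- r$values == "T"
  list(t_events = sum(tr),
       t_letters = sum(r$lengths[tr]),
       multi_run_positions = as.integer(starts[tr & r$lengths >= 2L]))
}

#' Calibrate the per-repeat single-T rate
#'
#' @param t_events single-T event count of the calibration TR region
#'   (or its DNA, which is counted with [countTEvents()]).
#' @param n_repeats repeat count of the calibration region (>= 1).
#' @return An [EstimatorCalibration-class]; the rate `t_events/n_repeats`
#'   is stored at full precision (display rounds to 2 decimals).
#' @examples
#' calibrateRate(362, 101)  # 3.58 T per repeat
#' @export
calibrateRate <- function(t_events, n_repeats) {
  multi <- integer(0)
  if (is.character(t_events) || methods::is(t_events, "XString")) {
    cnt <- countTEvents(t_events)
    t_events <- cnt$t_events
    multi <- cnt$multi_run_positions
  }
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  new("EstimatorCalibration", tEvents = as.integer(t_events),
      nRepeats = as.integer(n_repeats),
      rate = t_events / n_repeats,
      multiRunPositions = multi)
}

#' Estimate a repeat-number difference from a T-event difference
#'
#' `round(delta_t / rate)`, half away from zero.
#'
#' @param delta_t signed difference in single-T events.
#' @param calibration an [EstimatorCalibration-class] with rate > 0.
#' @return Signed integer repeat-number difference.
#' @examples
#' estimateRepeatDelta(13, calibrateRate(362, 101))  # 4
#' @export
estimateRepeatDelta <- function(delta_t, calibration) {
  if (!(calibration@rate > 0)) stop("calibration rate must be > 0")
  as.integer(.roundHalfAway(delta_t / calibration@rate))
}

#' Estimate a repeat count from a query's T events
#'
#' The calibration repeat count plus the estimated repeat-number
#' difference of the query against the calibration region.
#'
#' @param t_events_query single-T event count of the query TR region (or
#'   its DNA).
#' @param calibration an [EstimatorCalibration-class].
#' @param query_unit optional query unit template; a warning is issued
#'   when its identity to `calibration_unit` is < 0.9 (rate transfer
#'   across repeat motifs is unsupported).
#' @param calibration_unit optional calibration unit template.
#' @return Integer repeat-count estimate.
#' @examples
#' estimateRepeatCount(375, calibrateRate(362, 101))  # 105
#' @export
estimateRepeatCount <- function(t_events_query, calibration,
                                query_unit = NULL, calibration_unit = NULL) {
  if (is.character(t_events_query) || methods::is(t_events_query, "XString"))
    t_events_query <- countTEvents(t_events_query)$t_events
  if (!is.null(query_unit) && !is.null(calibration_unit)) {
    memo <- new.env(parent = emptyenv())
    id <- .unitIdentity(as.character(query_unit),
                        as.character(calibration_unit), memo)
    if (id < 0.9)
      warning("query and calibration unit templates share < 90% identity; ",
              "the per-repeat T rate may not transfer")
  }
  calibration@nRepeats +
    estimateRepeatDelta(t_events_query - calibration@tEvents, calibration)
}

#' Verify single-T invariance across frameshift adjustment
#'
#' Frameshift repair edits homopolymer runs; since template TR DNA has no
#' adjacent T pairs, edits confined to non-T runs leave the single-T
#' event count unchanged - the property that lets repeat numbers be
#' estimated from the raw consensus without arranging frameshifts.
#'
#' @param raw,adjusted the TR region before and after adjustment.
#' @return list: `invariant` (logical), `t_raw`, `t_adjusted`.
#' @export
verifyTInvariance <- function(raw, adjusted) {
  t1 <- countTEvents(raw)$t_events
  t2 <- countTEvents(adjusted)$t_events
  list(invariant = t1 == t2, t_raw = t1, t_adjusted = t2)
}
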
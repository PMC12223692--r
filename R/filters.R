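#' Construct a cohort-selection rule
#'
#' @param predictionAgeCutoff prediction age in years; children diagnosed or
#'   censored at or before this age are excluded (no features and no label
#'   are available for them at prediction time).
#' @param yobMax latest admissible birth year, or `NA` for none.
#' @param minFollowupYears minimum follow-up in years, or `NA` for none.
#' @param dropEarlyEvents if `FALSE` (default) the follow-up criterion only
#'   removes censored children with `time < minFollowupYears`, keeping
#'   observed events; if `TRUE` it removes all such children.
#' @return a validated [FilterSpec].
#' @export
filterSpec <- function(predictionAgeCutoff, yobMax = NA,
                       minFollowupYears = NA_real_, dropEarlyEvents = FALSE) {
  new("FilterSpec", yobMax = as.integer(yobMax),
      minFollowupYears = as.numeric(minFollowupYears),
      predictionAgeCutoff = as.numeric(predictionAgeCutoff),
      dropEarlyEvents = isTRUE(dropEarlyEvents))
}

setMethod("show", "FilterSpec", function(object) {
  parts <- sprintf("prediction age > %g", object@predictionAgeCutoff)
  if (!is.na(object@yobMax)) parts <- c(parts, sprintf("YOB <= %d", object@yobMax))
  if (!is.na(object@minFollowupYears))
    parts <- c(parts, sprintf("follow-up >= %g%s", object@minFollowupYears,
                              if (object@dropEarlyEvents) " (events too)" else
                                " (censored only)"))
  cat("FilterSpec:", paste(parts, collapse = ", "), "\n")
  invisible(object)
})

#' Apply a cohort-selection rule
#'
#' Removes (i) children born after `yobMax`, (ii) children failing the
#' minimum-follow-up criterion (by default only censored children with
#' `time < minFollowupYears`; see [filterSpec()]), and (iii) children with
#' `time <= predictionAgeCutoff`, i.e. diagnosed or censored before the
#' prediction age. Returns a new cohort; the input is not modified. The
#' operation is idempotent.
#'
#' @param cohort a non-empty [PatientCohort].
#' @param filter a [FilterSpec].
#' @return the filtered [PatientCohort].
#' @export
applyFilter <- function(cohort, filter) {
  validObject(filter)
  p <- cohort@patients
  .stopIfNot(nrow(p) > 0L, "cannot filter an empty cohort")
  keep <- rep(TRUE, nrow(p))
  if (!is.na(filter@yobMax)) keep <- keep & p$birth_year <= filter@yobMax
  if (!is.na(filter@minFollowupYears)) {
    short <- p$time < filter@minFollowupYears
    if (!filter@dropEarlyEvents) short <- short & p$event == 0L
    keep <- keep & !short
  }
  keep <- keep & p$time > filter@predictionAgeCutoff
  .stopIfNot(any(keep), "filter removed every patient")
  subsetCohort(cohort, p$patient_id[keep])
}

#' Truncate feature sequences at the prediction age
#'
#' Restricts every code sequence to events strictly before the prediction-age
#' cutoff AND strictly before the child's (latent) diagnosis time, preventing
#' post-diagnosis leakage into the features. All other fields are preserved;
#' empty sequences are allowed (the encoder handles them via padding).
#'
#' @param cohort a [PatientCohort] whose patients pass the filter for this
#'   cutoff.
#' @param predictionAgeCutoff positive age in years.
#' @return a new [PatientCohort] with truncated code sequences.
#' @export
truncateFeatures <- function(cohort, predictionAgeCutoff) {
  .stopIfNot(predictionAgeCutoff > 0, "predictionAgeCutoff must be > 0")
  cds <- cohort@codes
  if (nrow(cds)) {
    E <- cohort@patients$event_time[match(cds$patient_id,
                                          cohort@patients$patient_id)]
    keep <- cds$age < predictionAgeCutoff & cds$age < E
    cds <- cds[keep, , drop = FALSE]
    rownames(cds) <- NULL
  }
  new("PatientCohort", patients = cohort@patients, codes = cds,
      metadata = cohort@metadata)
}

#' Rescale the censoring distribution (semisynthetic censoring)
#'
#' Scales every censoring time by `maxAge / max(censoring_time)` so the
#' maximum censoring age in the output equals `maxAge` exactly, then
#' recomputes `time = min(event_time, C')` and the event indicator. Latent
#' event times are unchanged; events overtaken by the new censoring time
#' become censored, so the number of observed events is non-increasing. Code
#' sequences are re-truncated at the new observed times to keep the cohort
#' invariants.
#'
#' @param cohort a non-empty [PatientCohort].
#' @param maxAge positive target maximum censoring age in years.
#' @return a new [PatientCohort] with rescaled censoring.
#' @export
applySemisyntheticCensoring <- function(cohort, maxAge) {
  p <- cohort@patients
  .stopIfNot(nrow(p) > 0L, "cohort is empty")
  .stopIfNot(maxAge > 0, "maxAge must be > 0")
  m <- max(p$censoring_time)
  .stopIfNot(is.finite(m) && m > 0, "maximum censoring time must be positive and finite")
  p$censoring_time <- p$censoring_time * (maxAge / m)
  p$time <- pmin(p$event_time, p$censoring_time)
  p$event <- as.integer(p$event_time <= p$censoring_time)
  cds <- cohort@codes
  if (nrow(cds)) {
    tt <- p$time[match(cds$patient_id, p$patient_id)]
    cds <- cds[cds$age < tt, , drop = FALSE]
    rownames(cds) <- NULL
  }
  new("PatientCohort", patients = p, codes = cds, metadata = cohort@metadata)
}
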
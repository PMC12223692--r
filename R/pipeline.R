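#' Random train / validation / test partition
#'
#' Patient-level partition into fractions (default 60/20/20). Counts are the
#' floors of `n * fractions` with the remainder distributed by largest
#' fractional part, so exact fractions give exact sizes. Deterministic given
#' `seed`; the three parts are disjoint and their union is the input cohort.
#'
#' @param cohort a [PatientCohort].
#' @param fractions three non-negative numbers summing to 1 (tolerance 1e-9).
#' @param seed integer seed.
#' @return named list of [PatientCohort]s: `train`, `validation`, `test`.
#' @export
splitCohort <- function(cohort, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  .stopIfNot(length(fractions) == 3L && abs(sum(fractions) - 1) < 1e-9,
             "fractions must be three values summing to 1")
  n <- nPatients(cohort)
  raw <- n * fractions
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  ids <- withSeed(seed, sample(cohort@patients$patient_id))
  bounds <- cumsum(sizes)
  list(train = subsetCohort(cohort, ids[seq_len(bounds[1])]),
       validation = subsetCohort(cohort,
                                 ids[(bounds[1] + 1L):bounds[2]]),
       test = subsetCohort(cohort, ids[(bounds[2] + 1L):bounds[3]]))
}

#' Construct a model setup
#'
#' @param kind `"DTNN"`, `"BC"` or `"DCPH"`.
#' @param filter the [FilterSpec] applied when training this setup.
#' @param label display name.
#' @return a [ModelSetup].
#' @export
modelSetup <- function(kind, filter, label) {
  new("ModelSetup", kind = match.arg(kind, c("DTNN", "BC", "DCPH")),
      filter = filter, label = label)
}

#' The five canonical model setups
#'
#' Three binary classifiers trained under increasingly aggressive filtering
#' (a loose birth-year cutoff, a stricter birth-year cutoff, a minimum
#' follow-up requirement) plus the two time-to-event models under the loose
#' birth-year cutoff.
#'
#' @param predictionAgeCutoff the condition-specific prediction age.
#' @param yobMax loose birth-year cutoff (e.g. 2020).
#' @param yobStrict strict birth-year cutoff (e.g. 2018).
#' @param minFollowup minimum follow-up for the aggressive filter (years).
#' @return named list of [ModelSetup]s.
#' @export
canonicalSetups <- function(predictionAgeCutoff, yobMax = 2020L,
                            yobStrict = 2018L, minFollowup = 5) {
  loose <- filterSpec(predictionAgeCutoff, yobMax = yobMax)
  strict <- filterSpec(predictionAgeCutoff, yobMax = yobStrict)
  followup <- filterSpec(predictionAgeCutoff, yobMax = yobStrict,
                         minFollowupYears = minFollowup)
  list(
    BC_loose = modelSetup("BC", loose, sprintf("BC_YOB<=%d", yobMax)),
    BC_strict = modelSetup("BC", strict, sprintf("BC_YOB<=%d", yobStrict)),
    BC_followup = modelSetup("BC", followup,
                             sprintf("BC_t>=%g", minFollowup)),
    DTNN = modelSetup("DTNN", loose, sprintf("DTNN_YOB<=%d", yobMax)),
    DCPH = modelSetup("DCPH", loose, sprintf("DCPH_YOB<=%d", yobMax))
  )
}

#' Censoring-aware evaluation of one trained model
#'
#' Computes, on a common test cohort: time-varying AUC and AP at each
#' requested time, regular AUC/AP on observed labels, Harrell's concordance,
#' and the censoring concordance, each with a percentile-bootstrap CI.
#'
#' @param model a [TTEModel].
#' @param test feature-truncated test [PatientCohort].
#' @param evalTimes evaluation ages for the time-varying metrics.
#' @param horizonTime age used for the scalar risk score (defaults to the
#'   largest evaluation time).
#' @param nBoot bootstrap resamples (default 100).
#' @param seed integer bootstrap seed.
#' @param label model label recorded in the output.
#' @return data.frame of [metricEstimate()] rows with a `model` column.
#' @export
evaluateModel <- function(model, test, evalTimes, horizonTime = max(evalTimes),
                          nBoot = 100L, seed = 1L, label = model@kind) {
  p <- test@patients
  n <- nrow(p)
  scoresAt <- lapply(evalTimes, function(t) predictRisk(model, test, t))
  names(scoresAt) <- as.character(evalTimes)
  horizonScores <- predictRisk(model, test, horizonTime)

  rows <- list()
  addBoot <- function(name, t, statistic, seedOff) {
    rows[[length(rows) + 1L]] <<- bootstrapCi(
      statistic, n, nBoot = nBoot, seed = seed + seedOff,
      metricName = name, evalTime = t)
  }
  for (i in seq_along(evalTimes)) {
    t <- evalTimes[i]
    sc <- scoresAt[[i]]
    addBoot("auc_t", t, function(idx)
      aucT(sc[idx], p$time[idx], p$event[idx], t), 100L + i)
    addBoot("ap_t", t, function(idx)
      apT(sc[idx], p$time[idx], p$event[idx], t), 200L + i)
  }
  addBoot("regular_auc", NA_real_, function(idx)
    regularAuc(horizonScores[idx], p$event[idx]), 301L)
  addBoot("regular_ap", NA_real_, function(idx)
    regularAp(horizonScores[idx], p$event[idx]), 302L)
  addBoot("harrell_c", NA_real_, function(idx)
    harrellC(horizonScores[idx], p$time[idx], p$event[idx]), 303L)
  addBoot("censoring_concordance", NA_real_, function(idx)
    censoringConcordance(1 - horizonScores[idx], p$time[idx], p$event[idx]),
    304L)
  out <- do.call(rbind, rows)
  out <- cbind(model = label, out)
  rownames(out) <- NULL
  out
}

#' Per-subgroup prediction summaries
#'
#' Summarises predicted probabilities within the levels of one attribute.
#' For the ordered attributes (`birth_year`, `followup_length` = whole years
#' of observed follow-up) levels are ordered and a Spearman rank correlation
#' between predictions and the level value is reported.
#'
#' @param predictions per-patient predicted probabilities.
#' @param cohort the matching [PatientCohort].
#' @param attribute one of `"birth_year"`, `"followup_length"`, `"sex"`,
#'   `"race"`, `"insurance"`.
#' @return data.frame with one row per level (`level`, `n`, `mean`,
#'   `median`, `q25`, `q75`) plus `rank_correlation` / `rank_p` columns
#'   (NA for unordered attributes).
#' @export
subgroupSummary <- function(predictions, cohort,
                            attribute = c("birth_year", "followup_length",
                                          "sex", "race", "insurance")) {
  attribute <- match.arg(attribute)
  p <- cohort@patients
  .stopIfNot(length(predictions) == nrow(p),
             "predictions must align with the cohort")
  vals <- switch(attribute,
                 followup_length = floor(p$time),
                 p[[attribute]])
  ordered <- attribute %in% c("birth_year", "followup_length")
  lv <- if (ordered) sort(unique(vals)) else sort(unique(as.character(vals)))
  rows <- lapply(lv, function(l) {
    sel <- vals == l
    q <- stats::quantile(predictions[sel], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(attribute = attribute, level = as.character(l), n = sum(sel),
               mean = mean(predictions[sel]), median = q[2],
               q25 = q[1], q75 = q[3], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (ordered && length(lv) > 1L) {
    ct <- suppressWarnings(
      stats::cor.test(predictions, as.numeric(vals), method = "spearman"))
    out$rank_correlation <- unname(ct$estimate)
    out$rank_p <- ct$p.value
  } else {
    out$rank_correlation <- NA_real_
    out$rank_p <- NA_real_
  }
  rownames(out) <- NULL
  out
}

#' Evaluate a model on strata excluded by its training filter
#'
#' Flags every birth-year and follow-up stratum of `cohort` as
#' in-distribution or out-of-distribution (OOD) relative to the setup's
#' filter (later birth years, shorter follow-up), summarises predictions per
#' stratum, and computes a calibration curve on the pooled OOD patients.
#'
#' @param model the trained [TTEModel].
#' @param cohort an evaluation [PatientCohort] (feature-truncated) that
#'   includes patients outside the setup's filter.
#' @param setup the [ModelSetup] the model was trained under.
#' @param t evaluation age for predictions and calibration.
#' @return list with `strata` (per-stratum summaries with an `ood` flag) and
#'   `oodCalibration` (a [calibrationCurve()] data.frame).
#' @export
oodEvaluation <- function(model, cohort, setup, t) {
  p <- cohort@patients
  fs <- setup@filter
  preds <- predictRisk(model, cohort, t)
  oodPatient <- rep(FALSE, nrow(p))
  if (!is.na(fs@yobMax)) oodPatient <- oodPatient | p$birth_year > fs@yobMax
  if (!is.na(fs@minFollowupYears))
    oodPatient <- oodPatient | p$time < fs@minFollowupYears
  .stopIfNot(any(oodPatient), "no OOD patients relative to this setup")

  yob <- subgroupSummary(preds, cohort, "birth_year")
  yob$ood <- if (is.na(fs@yobMax)) FALSE else
    as.numeric(yob$level) > fs@yobMax
  fol <- subgroupSummary(preds, cohort, "followup_length")
  fol$ood <- if (is.na(fs@minFollowupYears)) FALSE else
    as.numeric(fol$level) < fs@minFollowupYears
  strata <- rbind(yob, fol)

  oodCal <- calibrationCurve(preds[oodPatient], p$time[oodPatient],
                             p$event[oodPatient], t)
  list(strata = strata, oodCalibration = oodCal)
}
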
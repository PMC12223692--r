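#' @import methods
NULL

#' Simulation configuration for a synthetic pediatric EHR cohort
#'
#' Encodes the statistical structure of a longitudinal diagnosis cohort:
#' covariate-dependent discrete-time event hazards on yearly age bins, a fixed
#' data-extraction date that induces birth-year-driven administrative
#' censoring, optional exponential dropout censoring, a prevalence trend over
#' birth year, and a marked point process of medical codes whose composition
#' carries both risk signal (risk codes enriched in high-hazard children) and
#' birth-era signal (era codes whose usage drifts with birth year, emulating
#' secular drift in coding practice).
#'
#' @slot nPatients number of children to simulate.
#' @slot birthYearRange integer `c(min, max)` of birth years, `min < max`.
#' @slot extractionYear decimal year of the administrative data-extraction
#'   date; administrative censoring age is `extractionYear - birthYear - u`
#'   with `u ~ Unif(0,1)` the within-year birth offset.
#' @slot dropoutRate per-year hazard of loss to follow-up (exponential); 0
#'   disables dropout censoring.
#' @slot baselineHazards per-bin discrete event hazards on yearly age bins
#'   `(0,1], (1,2], ...`; the vector length sets the event horizon.
#' @slot covariateEffects named numeric of log-hazard-ratios keyed as
#'   `"attribute:level"`, e.g. `c("sex:male" = 0.5)`.
#' @slot prevalenceTrend additive log-hazard drift per birth year (centred at
#'   `referenceYear`).
#' @slot referenceYear centring year for the prevalence trend.
#' @slot vocabularySize number of distinct medical-code tokens.
#' @slot meanCodesPerYear expected code events per follow-up year.
#' @slot riskCodeFraction fraction of the vocabulary acting as risk codes.
#' @slot eraCodeFraction fraction of the vocabulary acting as era codes.
#' @slot riskEnrichment log-scale enrichment of risk codes per unit of the
#'   latent risk propensity.
#' @slot eraDrift log-scale drift of era-code usage per birth year.
#' @slot riskEffect log-hazard contribution per unit latent risk propensity
#'   (the code-burden effect on the hazard).
#' @slot hazardLink `"logit"` (default) or `"cloglog"`; cloglog makes the
#'   discrete hazards exactly proportional in the piecewise-exponential sense.
#' @slot immuneFraction fraction of children that can never experience the
#'   event (stress-test option; default 0).
#' @slot categoryFreqs named list of category frequency vectors for `sex`,
#'   `race`, `insurance`.
#' @slot seed integer simulation seed.
#' @export
setClass("CohortConfig",
  representation(
    nPatients = "integer", birthYearRange = "integer",
    extractionYear = "numeric", dropoutRate = "numeric",
    baselineHazards = "numeric", covariateEffects = "numeric",
    prevalenceTrend = "numeric", referenceYear = "numeric",
    vocabularySize = "integer", meanCodesPerYear = "numeric",
    riskCodeFraction = "numeric", eraCodeFraction = "numeric",
    riskEnrichment = "numeric", eraDrift = "numeric", riskEffect = "numeric",
    hazardLink = "character", immuneFraction = "numeric",
    categoryFreqs = "list", seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msgs <- character()
  if (object@nPatients < 1L) msgs <- c(msgs, "nPatients must be >= 1")
  if (length(object@birthYearRange) != 2L || anyNA(object@birthYearRange) ||
      object@birthYearRange[1] >= object@birthYearRange[2])
    msgs <- c(msgs, "birthYearRange must be a nondegenerate [min, max] pair")
  if (length(object@baselineHazards) < 1L ||
      any(object@baselineHazards < 0 | object@baselineHazards >= 1))
    msgs <- c(msgs, "baselineHazards must all lie in [0, 1)")
  if (object@dropoutRate < 0) msgs <- c(msgs, "dropoutRate must be >= 0")
  if (!object@hazardLink %in% c("logit", "cloglog"))
    msgs <- c(msgs, "hazardLink must be 'logit' or 'cloglog'")
  if (object@riskCodeFraction < 0 || object@eraCodeFraction < 0 ||
      object@riskCodeFraction + object@eraCodeFraction > 1)
    msgs <- c(msgs, "risk/era code fractions must be >= 0 and sum to <= 1")
  if (object@immuneFraction < 0 || object@immuneFraction >= 1)
    msgs <- c(msgs, "immuneFraction must lie in [0, 1)")
  if (object@vocabularySize < 3L) msgs <- c(msgs, "vocabularySize must be >= 3")
  if (object@meanCodesPerYear < 0) msgs <- c(msgs, "meanCodesPerYear must be >= 0")
  if (!all(c("sex", "race", "insurance") %in% names(object@categoryFreqs)))
    msgs <- c(msgs, "categoryFreqs must contain sex, race and insurance")
  if (length(msgs)) msgs else TRUE
})

#' A simulated cohort of children with code sequences and survival outcomes
#'
#' Container for one simulated cohort. `patients` holds one row per child with
#' demographic attributes, the latent event time `event_time` (`Inf` when the
#' event never occurs), the censoring time `censoring_time`, the observed time
#' `time = min(event_time, censoring_time)` and the event indicator `event`.
#' `codes` is a long table of timestamped medical-code events, one row per
#' `(patient_id, age, code)`, with every age strictly below the patient's
#' observed time.
#'
#' @slot patients data.frame with columns `patient_id`, `birth_year`, `sex`,
#'   `race`, `insurance`, `event_time`, `censoring_time`, `time`, `event`.
#' @slot codes data.frame with columns `patient_id`, `age`, `code`.
#' @slot metadata list of provenance (config, seed).
#' @export
setClass("PatientCohort",
  representation(patients = "data.frame", codes = "data.frame",
                 metadata = "list")
)

.patientCols <- c("patient_id", "birth_year", "sex", "race", "insurance",
                  "event_time", "censoring_time", "time", "event")

setValidity("PatientCohort", function(object) {
  p <- object@patients
  msgs <- character()
  if (!all(.patientCols %in% names(p)))
    msgs <- c(msgs, paste("patients must have columns:",
                          paste(.patientCols, collapse = ", ")))
  if (!all(c("patient_id", "age", "code") %in% names(object@codes)))
    msgs <- c(msgs, "codes must have columns patient_id, age, code")
  if (length(msgs) == 0L && nrow(p) > 0L) {
    if (anyDuplicated(p$patient_id)) msgs <- c(msgs, "duplicate patient_id")
    if (any(p$censoring_time <= 0)) msgs <- c(msgs, "censoring_time must be > 0")
    if (!isTRUE(all.equal(p$time, pmin(p$event_time, p$censoring_time))))
      msgs <- c(msgs, "time must equal min(event_time, censoring_time)")
    if (!identical(as.integer(p$event),
                   as.integer(p$event_time <= p$censoring_time)))
      msgs <- c(msgs, "event must be 1 iff event_time <= censoring_time")
    if (nrow(object@codes) > 0L) {
      tt <- p$time[match(object@codes$patient_id, p$patient_id)]
      if (anyNA(tt)) msgs <- c(msgs, "codes reference unknown patient_id")
      else if (any(object@codes$age >= tt))
        msgs <- c(msgs, "all code ages must be strictly below the observed time")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' A cohort-selection rule
#'
#' Combines an optional birth-year cutoff, an optional minimum follow-up, and
#' a mandatory prediction-age cutoff (children diagnosed or censored at or
#' before the prediction age are excluded because no prediction can be made
#' for them). By default the follow-up criterion removes only censored
#' children with short follow-up, keeping events observed before the
#' threshold; `dropEarlyEvents = TRUE` removes every child with short
#' follow-up regardless of event status.
#'
#' @slot yobMax latest admissible birth year (`NA` = no birth-year criterion).
#' @slot minFollowupYears minimum follow-up in years (`NA` = none).
#' @slot predictionAgeCutoff prediction age in years (> 0).
#' @slot dropEarlyEvents logical follow-up-filter semantics switch.
#' @export
setClass("FilterSpec",
  representation(yobMax = "integer", minFollowupYears = "numeric",
                 predictionAgeCutoff = "numeric", dropEarlyEvents = "logical")
)

setValidity("FilterSpec", function(object) {
  msgs <- character()
  if (length(object@predictionAgeCutoff) != 1L ||
      is.na(object@predictionAgeCutoff) || object@predictionAgeCutoff <= 0)
    msgs <- c(msgs, "predictionAgeCutoff must be a single positive number")
  if (!is.na(object@minFollowupYears) && object@minFollowupYears < 0)
    msgs <- c(msgs, "minFollowupYears must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Discretization of the time horizon into bins
#'
#' Bins are left-open right-closed intervals `(start, e1], (e1, e2], ...` with
#' strictly increasing right edges; the last edge is the horizon `E_max`.
#' Times above the horizon belong to the beyond-horizon category, index
#' `nBins(grid) + 1`.
#'
#' @slot edges strictly increasing positive right bin edges; last = horizon.
#' @slot start left edge of the first bin (default 0).
#' @export
setClass("TimeGrid", representation(edges = "numeric", start = "numeric"))

setClassUnion("TimeGridOrNULL", c("TimeGrid", "NULL"))

setValidity("TimeGrid", function(object) {
  msgs <- character()
  if (length(object@edges) < 1L || any(diff(c(object@start, object@edges)) <= 0))
    msgs <- c(msgs, "edges must be strictly increasing and above start")
  if (object@start < 0) msgs <- c(msgs, "start must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Per-patient probability mass over time bins
#'
#' One row per patient, one column per [TimeGrid] bin plus a final
#' beyond-horizon column; rows are probability vectors (non-negative, summing
#' to 1 within 1e-6). The implied survival function is non-increasing in `t`
#' by construction.
#'
#' @slot probs numeric matrix, `nBins(grid) + 1` columns.
#' @slot grid the [TimeGrid] the columns refer to.
#' @export
setClass("DiscreteDistribution",
  representation(probs = "matrix", grid = "TimeGrid")
)

setValidity("DiscreteDistribution", function(object) {
  msgs <- character()
  if (ncol(object@probs) != length(object@grid@edges) + 1L)
    msgs <- c(msgs, "probs must have nBins + 1 columns (beyond-horizon included)")
  if (any(object@probs < -1e-9)) msgs <- c(msgs, "probabilities must be >= 0")
  if (nrow(object@probs) > 0L &&
      any(abs(rowSums(object@probs) - 1) > 1e-6))
    msgs <- c(msgs, "each row must sum to 1 within 1e-6")
  if (length(msgs)) msgs else TRUE
})

#' A trained prediction model (shared encoder + one head)
#'
#' Opaque handle returned by [trainModel()]: the frozen embedding table, the
#' encoder and head weights, the selected hyperparameters, the grid-search /
#' epoch history, and (for DCPH) the Breslow baseline cumulative hazard
#' estimated on the training data.
#'
#' @slot kind `"DTNN"`, `"BC"` or `"DCPH"`.
#' @slot params list of weight matrices/vectors (W1, b1, W2, b2, W3, b3).
#' @slot embeddings token-by-dimension embedding matrix with `.pad` and
#'   `.oov` rows fixed at zero.
#' @slot encoder encoder configuration list (see [encoderConfig()]).
#' @slot grid the [TimeGrid] of the DTNN head (`NULL` for BC/DCPH).
#' @slot baseline list with `times` and `cumhaz` (DCPH Breslow baseline).
#' @slot attrLevels named list of attribute levels used for one-hot input.
#' @slot hyperparams list with the selected `learningRate` and `weightDecay`.
#' @slot history data.frame of per-candidate, per-epoch training/validation
#'   losses.
#' @slot trainConfig the training configuration used.
#' @export
setClass("TTEModel",
  representation(kind = "character", params = "list", embeddings = "matrix",
                 encoder = "list", grid = "TimeGridOrNULL", baseline = "list",
                 attrLevels = "list", hyperparams = "list",
                 history = "data.frame", trainConfig = "list")
)

#' One of the five canonical model setups
#'
#' @slot kind `"DTNN"`, `"BC"` or `"DCPH"`.
#' @slot filter the [FilterSpec] applied to the training/validation data.
#' @slot label display label, e.g. `"BC_t>=5"`.
#' @export
setClass("ModelSetup",
  representation(kind = "character", filter = "FilterSpec", label = "character")
)

#' End-to-end experiment output
#'
#' @slot metrics tidy data.frame: one row per (model, metric, eval_time) with
#'   point estimate and bootstrap CI.
#' @slot calibration long data.frame of calibration-curve points.
#' @slot subgroups data.frame of per-attribute-level prediction summaries.
#' @slot provenance list of seeds, configs and sizes.
#' @slot models named list of fitted [TTEModel] handles.
#' @export
setClass("ExperimentReport",
  representation(metrics = "data.frame", calibration = "data.frame",
                 subgroups = "data.frame", provenance = "list",
                 models = "list")
)
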
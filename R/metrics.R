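#' Time-varying AUC under right-censoring
#'
#' Discrimination between children diagnosed by age `t` (cases:
#' `event == 1 & time <= t`) and children known to remain event-free beyond
#' `t` (controls: `time > t`). Children censored at or before `t` carry no
#' label information at `t` and are excluded. Returns the Mann-Whitney
#' probability that a random case outscores a random control, ties counted
#' one half.
#'
#' @param scores risk scores at time `t` (higher = more likely diagnosed).
#' @param times observed times `min(E, C)`.
#' @param events event indicators (1 diagnosed, 0 censored).
#' @param t evaluation age (> 0).
#' @return the time-varying AUC in `[0, 1]`.
#' @export
aucT <- function(scores, times, events, t) {
  sel <- .casesControlsAt(times, events, t)
  .mannWhitney(scores[sel$case | sel$control], sel$case[sel$case | sel$control])
}

.casesControlsAt <- function(times, events, t) {
  .stopIfNot(length(times) == length(events) && length(times) == length(times),
             "times and events must have equal length")
  .stopIfNot(t > 0, "t must be > 0")
  case <- events == 1 & times <= t
  control <- times > t
  .stopIfNot(any(case), "no cases at the requested time")
  .stopIfNot(any(control), "no controls at the requested time")
  list(case = case, control = control)
}

.mannWhitney <- function(scores, isCase) {
  m <- sum(isCase); n <- sum(!isCase)
  r <- rank(scores) # midranks give the ties-count-half convention
  (sum(r[isCase]) - m * (m + 1) / 2) / (m * n)
}

#' Time-varying average precision under right-censoring
#'
#' Average precision over the same case/control sets as [aucT()] (children
#' censored at or before `t` excluded): the precision at each case's rank in
#' descending-score order, averaged over cases. Tied scores are handled by
#' evaluating precision at distinct score thresholds, which reduces to
#' precision-at-case-ranks when scores are distinct.
#'
#' @inheritParams aucT
#' @return the time-varying average precision in `(0, 1]`.
#' @export
apT <- function(scores, times, events, t) {
  sel <- .casesControlsAt(times, events, t)
  keep <- sel$case | sel$control
  .averagePrecision(scores[keep], as.integer(sel$case[keep]))
}

.averagePrecision <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  tp <- cumsum(lab)
  pos <- seq_along(lab)
  # evaluate at the last index of each tied-score block
  last <- pos[!duplicated(sc, fromLast = TRUE)]
  tpAt <- tp[last]
  prec <- tpAt / last
  dTP <- diff(c(0, tpAt))
  sum(prec * dTP) / sum(lab)
}

#' Standard AUC / AP on observed-diagnosis labels
#'
#' The conventional binary metrics that treat every censored child as a
#' negative regardless of follow-up length: they cannot distinguish
#' non-diagnosed children with short versus long follow-up, which is what
#' inflates them under heavy censoring.
#'
#' @param scores risk scores.
#' @param labels observed-diagnosis indicators `S`.
#' @return the AUC (or AP) as a single number.
#' @export
regularAuc <- function(scores, labels) {
  .stopIfNot(length(unique(labels)) == 2L, "labels must contain both classes")
  .mannWhitney(scores, labels == 1)
}

#' @rdname regularAuc
#' @export
regularAp <- function(scores, labels) {
  .stopIfNot(length(unique(labels)) == 2L, "labels must contain both classes")
  .averagePrecision(scores, as.integer(labels == 1))
}

#' Harrell's concordance index
#'
#' Over comparable pairs (`times[i] < times[j]` with `events[i] == 1`), the
#' fraction where the earlier-event child has the higher score, ties in
#' score counted one half.
#'
#' @inheritParams aucT
#' @param scores risk scores (higher = earlier event expected).
#' @return the concordance index in `[0, 1]`.
#' @export
harrellC <- function(scores, times, events) {
  .stopIfNot(length(scores) == length(times) && length(times) == length(events),
             "inputs must have equal length")
  evIdx <- which(events == 1)
  num <- 0; den <- 0
  for (i in evIdx) {
    later <- times > times[i]
    nComp <- sum(later)
    if (nComp == 0L) next
    den <- den + nComp
    num <- num + sum(scores[i] > scores[later]) +
      0.5 * sum(scores[i] == scores[later])
  }
  .stopIfNot(den > 0, "no comparable pairs")
  num / den
}

#' Concordance between non-event predictions and censoring times
#'
#' Harrell-style concordance restricted to censored children, treating the
#' censoring time as the outcome (every censored child "experiences"
#' censoring) and the predicted non-event probability as the score. Under a
#' sound model, predictions carry no information about follow-up length and
#' the value is about 0.5; values above 0.5 flag the pathological dependence
#' of predictions on the censoring distribution.
#'
#' @param noneventScores predicted non-event probabilities (1 - predicted
#'   event probability).
#' @param censorTimes observed times.
#' @param events event indicators; only `events == 0` children are used.
#' @return the censoring concordance in `[0, 1]`.
#' @export
censoringConcordance <- function(noneventScores, censorTimes, events) {
  cen <- events == 0
  .stopIfNot(sum(cen) >= 2L, "need at least two censored patients")
  harrellC(noneventScores[cen], censorTimes[cen], rep(1L, sum(cen)))
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of `S(t) = P(T > t)` (right-continuous step
#' function, `S(0) = 1`), computed via [survival::survfit()]. Censored
#' observations shrink the risk set without introducing steps.
#'
#' @param times observed times.
#' @param events event indicators.
#' @return a [KMEstimate].
#' @export
kmEstimate <- function(times, events) {
  .stopIfNot(length(times) > 0L, "times must be non-empty")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  se <- fit$surv * fit$std.err # Greenwood, delta method from log scale
  se[!is.finite(se)] <- 0
  new("KMEstimate", times = as.numeric(fit$time),
      survival = as.numeric(fit$surv), survSE = as.numeric(se),
      nRisk = as.numeric(fit$n.risk), nEvent = as.numeric(fit$n.event))
}

#' Kaplan-Meier survival curve
#'
#' @slot times increasing observed times at which the curve is tabulated.
#' @slot survival the product-limit survival probabilities at those times.
#' @slot survSE Greenwood standard errors of the survival probabilities.
#' @slot nRisk,nEvent risk-set sizes and event counts.
#' @export
setClass("KMEstimate",
  representation(times = "numeric", survival = "numeric", survSE = "numeric",
                 nRisk = "numeric", nEvent = "numeric")
)

setMethod("show", "KMEstimate", function(object) {
  cat(sprintf("KMEstimate on %d time points; S(max) = %.3f\n",
              length(object@times), min(c(1, object@survival))))
  invisible(object)
})

#' @describeIn kmEstimate evaluate `S(t)` at arbitrary times (right-continuous
#'   step lookup; 1 before the first observed time).
#' @param km a [KMEstimate].
#' @param t times at which to evaluate the survival function.
#' @export
kmSurvivalAt <- function(km, t) {
  if (length(km@times) == 0L) return(rep(1, length(t)))
  idx <- findInterval(t, km@times)
  c(1, km@survival)[idx + 1L]
}

#' @describeIn kmEstimate Greenwood standard error of `S(t)` (0 before the
#'   first observed time).
#' @export
kmSurvivalSEAt <- function(km, t) {
  if (length(km@times) == 0L) return(rep(0, length(t)))
  idx <- findInterval(t, km@times)
  c(0, km@survSE)[idx + 1L]
}
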
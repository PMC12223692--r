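#' Discrete-time survival likelihood loss
#'
#' The maximum-likelihood loss of the discrete-time head. For an observed
#' event in bin `tBin` the loss is `-log` of that bin's mass; for a
#' censoring time in bin `tBin` it is `-log` of the total mass strictly
#' after the bin (the survival probability beyond the censoring interval,
#' which includes the beyond-horizon mass). Probabilities are clamped at
#' 1e-12 before taking logs.
#'
#' @param probs probability vector over `nBins + 1` categories (last =
#'   beyond-horizon), or a matrix with one row per observation.
#' @param tBin bin index in `1..nBins` containing the observed time.
#' @param s event indicator (1 event, 0 censored).
#' @return non-negative loss value(s), one per observation.
#' @export
dtnnLoss <- function(probs, tBin, s) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  K <- ncol(probs) - 1L
  .stopIfNot(all(tBin >= 1L & tBin <= K), "tBin out of range")
  n <- nrow(probs)
  tBin <- rep_len(tBin, n); s <- rep_len(s, n)
  eventMass <- probs[cbind(seq_len(n), tBin)]
  survMass <- vapply(seq_len(n), function(i)
    sum(probs[i, (tBin[i] + 1L):(K + 1L)]), numeric(1))
  -log(.clampProb(ifelse(s == 1, eventMass, survMass)))
}

# one likelihood component: per-row loss and unnormalised dlogits
.dtnnComponent <- function(probs, tBin, s) {
  n <- nrow(probs); K <- ncol(probs) - 1L
  eventMass <- probs[cbind(seq_len(n), tBin)]
  after <- outer(tBin, seq_len(K + 1L), `<`) # TRUE for bins strictly after tBin
  survMass <- rowSums(probs * after)
  loss <- -log(.clampProb(ifelse(s == 1, eventMass, survMass)))
  dl <- probs
  ev <- s == 1
  if (any(ev))
    dl[ev, ] <- dl[ev, , drop = FALSE] -
      (col(dl[ev, , drop = FALSE]) == tBin[ev])
  if (any(!ev)) {
    pc <- probs[!ev, , drop = FALSE]
    dl[!ev, ] <- pc - pc * after[!ev, , drop = FALSE] /
      pmax(survMass[!ev], 1e-12)
  }
  list(loss = loss, dl = dl)
}

# mean (weighted) loss + d(mean loss)/d(logits) for a batch of DTNN outputs;
# censored-inside-bin observations carry two half-weight components
.dtnnLossGrad <- function(logits, tBin, s, w = NULL, tBin2 = NULL,
                          w2 = NULL) {
  probs <- .softmax(logits)
  n <- nrow(probs)
  if (is.null(w)) w <- rep(1, n)
  c1 <- .dtnnComponent(probs, tBin, s)
  loss <- w * c1$loss
  dl <- w * c1$dl
  if (!is.null(tBin2) && any(b <- !is.na(tBin2))) {
    c2 <- .dtnnComponent(probs[b, , drop = FALSE], tBin2[b],
                         rep(0L, sum(b)))
    loss[b] <- loss[b] + w2[b] * c2$loss
    dl[b, ] <- dl[b, , drop = FALSE] + w2[b] * c2$dl
  }
  list(loss = mean(loss), dOut = dl / n)
}

#' Binary cross-entropy of a probability against an observed label
#'
#' The BC head maps the representation to a log-odds; the predicted
#' probability is its logistic transform and is used unchanged at every
#' evaluation time.
#'
#' @param prob predicted probability in `(0, 1)`.
#' @param s observed-diagnosis label.
#' @return per-observation binary cross-entropy.
#' @export
bceLoss <- function(prob, s) {
  p <- .clampProb(prob)
  -(s * log(p) + (1 - s) * log(1 - p))
}

.bcLossGrad <- function(eta, s) {
  p <- stats::plogis(as.numeric(eta))
  list(loss = mean(bceLoss(p, s)),
       dOut = matrix((p - s) / length(s), ncol = 1L))
}

#' Cox negative partial log-likelihood (Breslow ties)
#'
#' @param logHazardRatios per-patient predicted log-hazard ratios.
#' @param times observed times.
#' @param events event indicators; at least one event is required.
#' @return the negative partial log-likelihood (Breslow tie handling);
#'   invariant to adding a constant to all log-hazard ratios.
#' @export
coxPartialLoglik <- function(logHazardRatios, times, events) {
  .stopIfNot(length(logHazardRatios) == length(times) &&
               length(times) == length(events), "inputs must have equal length")
  .stopIfNot(any(events == 1), "partial likelihood undefined without events")
  lp <- logHazardRatios - max(logHazardRatios) # location invariance, stable exp
  o <- order(times, decreasing = TRUE)
  lp <- lp[o]; tt <- times[o]; ev <- events[o]
  cumRisk <- cumsum(exp(lp)) # partial sums down the descending-time order
  # Breslow: every tied event shares the full risk set {j : T_j >= t}, i.e.
  # the partial sum at the END of its tied block
  denomAt <- stats::ave(cumRisk, tt, FUN = max)
  evIdx <- ev == 1
  -(sum(lp[evIdx]) - sum(log(denomAt[evIdx])))
}

# gradient of the batch-normalised negative partial log-likelihood
.coxLossGrad <- function(lp, times, events) {
  n <- length(lp)
  if (!any(events == 1)) return(NULL)
  lpc <- as.numeric(lp) - max(lp)
  o <- order(times, decreasing = TRUE)
  ro <- order(o)
  lps <- lpc[o]; tts <- times[o]; evs <- events[o]
  elp <- exp(lps)
  cumRisk <- cumsum(elp)
  denomAt <- stats::ave(cumRisk, tts, FUN = max) # full tied-block risk sets
  nev <- sum(evs)
  loss <- -(sum(lps[evs == 1]) - sum(log(denomAt[evs == 1]))) / nev
  # dloss/dlp_i = (e^{lp_i} * sum over events with t_k <= T_i of 1/denom_k
  #               - s_i) / nev; the sum runs over whole tied blocks
  w <- ifelse(evs == 1, 1 / denomAt, 0)
  revCumW <- rev(cumsum(rev(w)))          # sum over positions j >= i
  cumW <- stats::ave(revCumW, tts, FUN = max) # extend to whole tied block
  gs <- (elp * cumW - evs) / nev
  list(loss = loss, dOut = matrix(gs[ro], ncol = 1L))
}

#' Breslow baseline cumulative hazard
#'
#' Estimates the baseline cumulative hazard `H0(t)` from fitted log-hazard
#' ratios: at each distinct event time, the increment is the number of
#' events divided by the sum of `exp(lp)` over the risk set.
#'
#' @param logHazardRatios fitted log-hazard ratios on the training data.
#' @param times,events training outcomes.
#' @return list with `times` (distinct event times, increasing) and
#'   `cumhaz` (the cumulative hazard at those times).
#' @export
breslowBaseline <- function(logHazardRatios, times, events) {
  .stopIfNot(any(events == 1), "no events")
  lp <- as.numeric(logHazardRatios)
  evTimes <- sort(unique(times[events == 1]))
  inc <- vapply(evTimes, function(tk) {
    sum(events == 1 & times == tk) / sum(exp(lp[times >= tk]))
  }, numeric(1))
  list(times = evTimes, cumhaz = cumsum(inc))
}

#' Event probability from a deep Cox model
#'
#' `P(event by t) = 1 - exp(-H0(t) * exp(logHazardRatio))` under proportional
#' hazards, with the Breslow baseline carried flat beyond its last event
#' time. Non-decreasing in `t` and order-preserving in the log-hazard ratio
#' at every `t`.
#'
#' @param logHazardRatio predicted log-hazard ratio(s).
#' @param baseline a [breslowBaseline()] estimate.
#' @param t evaluation time (single value).
#' @return per-patient event probabilities by `t`.
#' @export
dcphSurvival <- function(logHazardRatio, baseline, t) {
  .stopIfNot(length(t) == 1L && t >= 0, "t must be a single non-negative time")
  H0 <- if (length(baseline$times) == 0L) 0 else {
    idx <- findInterval(t, baseline$times)
    if (idx == 0L) 0 else baseline$cumhaz[idx] # flat extrapolation beyond last
  }
  1 - exp(-H0 * exp(as.numeric(logHazardRatio)))
}
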
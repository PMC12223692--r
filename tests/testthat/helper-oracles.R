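# Brute-force reference implementations used as independent oracles.
# All of them enumerate pairs / risk sets explicitly and are only meant for
# small n.

bfAucT <- function(scores, times, events, t) {
  case <- which(events == 1 & times <= t)
  control <- which(times > t)
  num <- 0
  for (i in case) for (j in control) {
    num <- num + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  num / (length(case) * length(control))
}

bfApT <- function(scores, times, events, t) {
  case <- events == 1 & times <= t
  control <- times > t
  keep <- case | control
  bfAp(scores[keep], as.integer(case[keep]))
}

bfAp <- function(scores, labels) {
  # precision at each distinct score threshold, weighted by new cases found
  th <- sort(unique(scores), decreasing = TRUE)
  total <- 0; prevTP <- 0
  for (s in th) {
    sel <- scores >= s
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    total <- total + prec * (tp - prevTP)
    prevTP <- tp
  }
  total / sum(labels == 1)
}

bfHarrellC <- function(scores, times, events) {
  num <- 0; den <- 0
  n <- length(times)
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    for (j in seq_len(n)) {
      if (times[i] < times[j]) {
        den <- den + 1
        num <- num + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
      }
    }
  }
  num / den
}

bfCensoringConcordance <- function(noneventScores, censorTimes, events) {
  cen <- events == 0
  bfHarrellC(noneventScores[cen], censorTimes[cen], rep(1, sum(cen)))
}

bfCoxNegPLL <- function(lp, times, events) {
  evTimes <- sort(unique(times[events == 1]))
  ll <- 0
  for (tk in evTimes) {
    d <- which(events == 1 & times == tk)
    denom <- sum(exp(lp[times >= tk]))
    ll <- ll + sum(lp[d]) - length(d) * log(denom)
  }
  -ll
}

# random survival instance with optional tied times
randomInstance <- function(n, tie = FALSE) {
  times <- if (tie) sample(1:5, n, replace = TRUE) else stats::rexp(n) + 0.1
  list(scores = stats::rnorm(n), times = times,
       events = stats::rbinom(n, 1, 0.6))
}
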
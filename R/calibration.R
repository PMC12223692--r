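#' Calibration curve against Kaplan-Meier observed incidence
#'
#' Groups children into quantile bins of predicted event probability at `t`
#' and, within each bin, compares the mean predicted probability to the
#' observed incidence `1 - S_KM(t)` estimated by the Kaplan-Meier
#' product-limit estimator inside the bin. Bins with fewer than `minBinSize`
#' children are merged with their neighbour to stabilise the KM estimate.
#'
#' @param predicted predicted event probabilities at `t`, in `[0, 1]`.
#' @param times observed times.
#' @param events event indicators.
#' @param t evaluation age.
#' @param nBins target number of quantile bins (default 10).
#' @param minBinSize minimum children per bin before merging (default 20).
#' @return data.frame with one row per bin: `bin`, `n`, `meanPredicted`,
#'   `observedIncidence`, and the Greenwood `observedSE` of the incidence.
#' @export
calibrationCurve <- function(predicted, times, events, t, nBins = 10L,
                             minBinSize = 20L) {
  .stopIfNot(all(predicted >= -1e-9 & predicted <= 1 + 1e-9),
             "predicted probabilities must lie in [0, 1]")
  .stopIfNot(length(predicted) == length(times), "length mismatch")
  qs <- stats::quantile(predicted, probs = seq(0, 1, length.out = nBins + 1L),
                        names = FALSE)
  breaks <- unique(qs)
  if (length(breaks) < 2L) { # constant predictions: one bin
    grp <- rep(1L, length(predicted))
  } else {
    grp <- cut(predicted, breaks = breaks, include.lowest = TRUE,
               labels = FALSE)
  }
  # merge small bins into the neighbour below (or above for the first)
  repeat {
    counts <- table(factor(grp, levels = sort(unique(grp))))
    lv <- as.integer(names(counts))
    small <- lv[counts < minBinSize]
    if (length(small) == 0L || length(lv) == 1L) break
    s <- small[1]
    target <- if (s == min(lv)) lv[which(lv > s)[1]] else max(lv[lv < s])
    grp[grp == s] <- target
  }
  lv <- sort(unique(grp))
  out <- do.call(rbind, lapply(seq_along(lv), function(i) {
    in_bin <- grp == lv[i]
    km <- kmEstimate(times[in_bin], events[in_bin])
    data.frame(bin = i, n = sum(in_bin),
               meanPredicted = mean(predicted[in_bin]),
               observedIncidence = 1 - kmSurvivalAt(km, t),
               observedSE = kmSurvivalSEAt(km, t))
  }))
  rownames(out) <- NULL
  out
}

#' A metric point estimate with bootstrap confidence interval
#'
#' @param metricName label of the metric.
#' @param point point estimate (from the unresampled data).
#' @param ciLow,ciHigh percentile-bootstrap interval bounds.
#' @param nBoot number of bootstrap resamples.
#' @param evalTime evaluation time, or `NA` for time-free metrics.
#' @return one-row data.frame with those columns.
#' @export
metricEstimate <- function(metricName, point, ciLow, ciHigh, nBoot,
                           evalTime = NA_real_) {
  data.frame(metric = metricName, eval_time = evalTime, point = point,
             ci_low = ciLow, ci_high = ciHigh, n_boot = nBoot,
             stringsAsFactors = FALSE)
}

#' Percentile-bootstrap confidence interval for a cohort-level metric
#'
#' Resamples patients with replacement `nBoot` times, evaluates `statistic`
#' on each resample, and forms the percentile interval at the requested
#' level. The point estimate comes from the unresampled data. Resamples on
#' which the metric is undefined (e.g. no cases) are redrawn; the number of
#' redraws is recorded in the `redraws` attribute.
#'
#' @param statistic function taking an integer index vector (positions into
#'   the cohort) and returning a single number.
#' @param n number of patients.
#' @param nBoot number of bootstrap resamples (default 100).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; the procedure is deterministic given it.
#' @param metricName,evalTime labels forwarded to [metricEstimate()].
#' @return a one-row [metricEstimate()] data.frame with a `redraws`
#'   attribute.
#' @export
bootstrapCi <- function(statistic, n, nBoot = 100L, level = 0.95, seed = 1L,
                        metricName = "metric", evalTime = NA_real_) {
  point <- statistic(seq_len(n))
  reps <- numeric(nBoot)
  redraws <- 0L
  withSeed(seed, {
    for (b in seq_len(nBoot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        val <- tryCatch(statistic(idx), error = function(e) NULL)
        if (!is.null(val) && is.finite(val)) break
        redraws <- redraws + 1L
        if (redraws > 1000L)
          stop("metric undefined on more than 1000 bootstrap resamples",
               call. = FALSE)
      }
      reps[b] <- val
    }
  })
  alpha <- (1 - level) / 2
  qs <- stats::quantile(reps, probs = c(alpha, 1 - alpha), names = FALSE,
                        type = 7)
  out <- metricEstimate(metricName, point, qs[1], qs[2], nBoot, evalTime)
  attr(out, "redraws") <- redraws
  attr(out, "replicates") <- reps
  out
}
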
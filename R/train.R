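.modelTargets <- function(kind, cohort, grid) {
  p <- cohort@patients
  if (kind == "DTNN") {
    K <- nBins(grid)
    s <- as.integer(p$event)
    # events: -log(mass of the bin containing the diagnosis age).
    # censored observations use the actuarial interval-censoring treatment:
    # a censoring age strictly inside bin k contributes survival through the
    # completed bins plus half a bin of exposure, -0.5 log S(k-1)
    # - 0.5 log S(k); integer-bin conventions ("survived the whole containing
    # bin" or "never entered it") bias a stratum's terminal-bin hazard by up
    # to half the censored count, which matters under heavy administrative
    # censoring. Censoring at a bin edge or beyond the horizon completes the
    # bin and contributes the full survival mass beyond it.
    containing <- pmin(binIndex(grid, p$time), K)
    completed <- pmin(findInterval(p$time + 1e-9, grid@edges), K)
    inside <- s == 0 & completed < containing
    tBin1 <- ifelse(s == 1, containing, completed)
    w1 <- ifelse(inside, 0.5, 1)
    # the half contribution -0.5 log S(k-1) vanishes when k-1 = 0 (S(0)=1)
    tBin2 <- ifelse(inside & completed >= 1L, completed, NA_integer_)
    hasB <- inside & completed >= 1L
    tBin1[inside] <- containing[inside]
    list(tBin = pmax(tBin1, 1L), w = w1,
         tBin2 = ifelse(hasB, pmax(tBin2, 1L), NA_integer_),
         w2 = ifelse(hasB, 0.5, 0), s = s)
  } else if (kind == "BC") {
    list(s = as.integer(p$event))
  } else {
    list(times = p$time, s = as.integer(p$event))
  }
}

.batchLossGrad <- function(kind, out, tg, idx) {
  switch(kind,
    DTNN = .dtnnLossGrad(out, tg$tBin[idx], tg$s[idx], tg$w[idx],
                         tg$tBin2[idx], tg$w2[idx]),
    BC = .bcLossGrad(out, tg$s[idx]),
    DCPH = .coxLossGrad(out, tg$times[idx], tg$s[idx]))
}

.validLoss <- function(kind, params, embeddings, feat, tg) {
  fw <- .forward(params, embeddings, feat)
  lg <- .batchLossGrad(kind, fw$out, tg, seq_len(feat$n))
  if (is.null(lg)) stop("validation set has no events", call. = FALSE)
  lg$loss
}

#' Train a prediction model with grid-searched hyperparameters
#'
#' Trains the shared encoder plus the requested head (discrete-time softmax
#' for DTNN, logistic for BC, log-hazard ratio with Cox partial likelihood
#' for DCPH) with Adam and decoupled weight decay. For every (learning rate,
#' weight decay) pair in the grids, training runs with early stopping on
#' validation loss and keeps the best-epoch weights; the pair with minimal
#' validation loss is returned. Deterministic given `config$seed`.
#'
#' @param kind `"DTNN"`, `"BC"` or `"DCPH"`.
#' @param train,valid filtered, feature-truncated [PatientCohort]s with
#'   disjoint patients.
#' @param config a [trainConfig()].
#' @param encoder an [encoderConfig()].
#' @param grid a [TimeGrid] (required for DTNN).
#' @param embeddings optional precomputed embedding table; when `NULL`, one
#'   is pretrained (or drawn at random) from the training sequences
#'   according to `encoder$embeddingInit`.
#' @return a [TTEModel].
#' @export
trainModel <- function(kind = c("DTNN", "BC", "DCPH"), train, valid,
                       config = trainConfig(), encoder = encoderConfig(),
                       grid = NULL, embeddings = NULL) {
  kind <- match.arg(kind)
  .stopIfNot(nPatients(train) > 0L && nPatients(valid) > 0L,
             "train and validation cohorts must be non-empty")
  .stopIfNot(length(intersect(train@patients$patient_id,
                              valid@patients$patient_id)) == 0L,
             "train and validation cohorts must be disjoint")
  if (kind == "DTNN") .stopIfNot(!is.null(grid), "DTNN requires a TimeGrid")

  if (is.null(embeddings)) {
    embSeed <- substreamSeed(config$seed, "embed")
    embeddings <- if (encoder$embeddingInit == "pretrained") {
      do.call(pretrainEmbeddings,
              c(list(sequences = codeSequences(train),
                     dim = encoder$embeddingDim, seed = embSeed),
                encoder$embeddingArgs))
    } else {
      randomEmbeddings(sort(unique(train@codes$code)), encoder$embeddingDim,
                       seed = embSeed)
    }
  }
  .stopIfNot(ncol(embeddings) == encoder$embeddingDim,
             "embedding dimension does not match the encoder configuration")

  attrLevels <- .attrLevelsFrom(train@patients)
  featTr <- .prepareFeatures(train, embeddings, encoder, attrLevels)
  featVa <- .prepareFeatures(valid, embeddings, encoder, attrLevels)
  tgTr <- .modelTargets(kind, train, grid)
  tgVa <- .modelTargets(kind, valid, grid)
  nOut <- if (kind == "DTNN") nBins(grid) + 1L else 1L
  nAttr <- ncol(featTr$attr)
  padRows <- match(c(".pad", ".oov"), rownames(embeddings))

  candidates <- expand.grid(lr = config$learningRateGrid,
                            wd = config$weightDecayGrid)
  history <- list()
  best <- NULL
  withSeed(config$seed, {
    initSeed <- substreamSeed(config$seed, "init")
    for (ci in seq_len(nrow(candidates))) {
      lr <- candidates$lr[ci]; wd <- candidates$wd[ci]
      params <- .initParams(encoder, nAttr, nOut, initSeed)
      emb <- embeddings
      state <- .adamInit(params)
      if (encoder$trainEmbeddings)
        embState <- list(m = emb * 0, v = emb * 0)
      bestVa <- Inf; bestAt <- 0L; wait <- 0L
      bestParams <- params; bestEmb <- emb
      for (ep in seq_len(config$maxEpochs)) {
        ord <- sample.int(featTr$n)
        nb <- ceiling(featTr$n / config$batchSize)
        epLoss <- 0; used <- 0L
        for (b in seq_len(nb)) {
          idx <- ord[((b - 1L) * config$batchSize + 1L):
                       min(b * config$batchSize, featTr$n)]
          fb <- .subsetFeatures(featTr, idx)
          fw <- .forward(params, emb, fb)
          lg <- .batchLossGrad(kind, fw$out, tgTr, idx)
          if (is.null(lg)) next # DCPH batch without events
          gr <- .backward(params, fw, fb, lg$dOut,
                          trainEmbeddings = encoder$trainEmbeddings,
                          padRows = padRows)
          upd <- .adamStep(params, gr[names(params)], state, lr, wd)
          params <- upd$params; state <- upd$state
          if (encoder$trainEmbeddings && !is.null(gr$embRows)) {
            gE <- emb * 0
            gE[gr$embRows, ] <- gr$emb
            embState$m <- 0.9 * embState$m + 0.1 * gE
            embState$v <- 0.999 * embState$v + 0.001 * gE^2
            emb <- emb - lr * (embState$m / (sqrt(embState$v) + 1e-8) +
                                 wd * emb)
            emb[padRows, ] <- 0
          }
          epLoss <- epLoss + lg$loss; used <- used + 1L
        }
        vaLoss <- .validLoss(kind, params, emb, featVa, tgVa)
        history[[length(history) + 1L]] <- data.frame(
          candidate = ci, learningRate = lr, weightDecay = wd, epoch = ep,
          trainLoss = if (used) epLoss / used else NA_real_,
          validLoss = vaLoss)
        if (vaLoss < bestVa - 1e-9) {
          bestVa <- vaLoss; bestAt <- ep; wait <- 0L
          bestParams <- params; bestEmb <- emb
        } else {
          wait <- wait + 1L
          if (wait >= config$patience) break
        }
      }
      if (is.null(best) || bestVa < best$validLoss) {
        best <- list(params = bestParams, emb = bestEmb, validLoss = bestVa,
                     lr = lr, wd = wd, epoch = bestAt)
      }
    }
  })

  baseline <- list()
  if (kind == "DCPH") {
    fw <- .forward(best$params, best$emb, featTr)
    baseline <- breslowBaseline(as.numeric(fw$out), tgTr$times, tgTr$s)
  }
  new("TTEModel", kind = kind, params = best$params, embeddings = best$emb,
      encoder = encoder, grid = if (kind == "DTNN") grid else NULL,
      baseline = baseline, attrLevels = attrLevels,
      hyperparams = list(learningRate = best$lr, weightDecay = best$wd,
                         validLoss = best$validLoss, bestEpoch = best$epoch),
      history = do.call(rbind, history), trainConfig = config)
}

setMethod("show", "TTEModel", function(object) {
  cat(sprintf("TTEModel<%s>: lr=%g, wd=%g, best validation loss %.4f\n",
              object@kind, object@hyperparams$learningRate,
              object@hyperparams$weightDecay, object@hyperparams$validLoss))
  invisible(object)
})

#' Model predictions
#'
#' `predictLinear()` returns the head's linear output (log-odds for BC,
#' log-hazard ratio for DCPH). `predictDistribution()` returns the DTNN's
#' per-patient [DiscreteDistribution]. `predictRisk()` returns the predicted
#' probability of diagnosis by age `t`: cumulative bin mass for DTNN, the
#' Breslow-baseline transform for DCPH, and the (time-constant) logistic
#' probability for BC, which by construction is identical at every `t`.
#'
#' @param model a [TTEModel].
#' @param cohort a feature-truncated [PatientCohort].
#' @param t evaluation age (ignored by BC).
#' @return numeric vector (or a [DiscreteDistribution]) aligned with
#'   `patients(cohort)`.
#' @export
setGeneric("predictRisk", function(model, cohort, t) {
  standardGeneric("predictRisk")
})

.forwardCohort <- function(model, cohort) {
  feat <- .prepareFeatures(cohort, model@embeddings, model@encoder,
                           model@attrLevels)
  .forward(model@params, model@embeddings, feat)
}

#' @rdname predictRisk
#' @export
setMethod("predictRisk", "TTEModel", function(model, cohort, t) {
  fw <- .forwardCohort(model, cohort)
  switch(model@kind,
    DTNN = eventProbabilityBy(
      discreteDistribution(.softmax(fw$out), model@grid), t),
    BC = stats::plogis(as.numeric(fw$out)),
    DCPH = dcphSurvival(as.numeric(fw$out), model@baseline, t))
})

#' @rdname predictRisk
#' @export
setGeneric("predictDistribution", function(model, cohort) {
  standardGeneric("predictDistribution")
})

#' @rdname predictRisk
#' @export
setMethod("predictDistribution", "TTEModel", function(model, cohort) {
  .stopIfNot(model@kind == "DTNN", "only DTNN predicts a distribution")
  fw <- .forwardCohort(model, cohort)
  discreteDistribution(.softmax(fw$out), model@grid)
})

#' @rdname predictRisk
#' @export
setGeneric("predictLinear", function(model, cohort) {
  standardGeneric("predictLinear")
})

#' @rdname predictRisk
#' @export
setMethod("predictLinear", "TTEModel", function(model, cohort) {
  .stopIfNot(model@kind %in% c("BC", "DCPH"),
             "linear predictions are defined for BC and DCPH heads")
  as.numeric(.forwardCohort(model, cohort)$out)
})
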
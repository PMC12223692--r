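#' Encoder configuration
#'
#' The shared encoder maps a child's code sequence to a fixed-length
#' representation: embedding lookup (frozen `.pad`/`.oov` zero rows), a
#' fully connected layer with ReLU applied in parallel to each token, global
#' mean pooling over the sequence dimension, and a second fully connected
#' layer with ReLU. Demographic attributes are appended one-hot to the
#' pooled representation before the prediction head. Sequences longer than
#' `maxSequenceLength` keep only the most recent events before the age
#' cutoff; shorter sequences are padded (padding contributes zero vectors).
#'
#' @param embeddingDim embedding dimension (default 256).
#' @param maxSequenceLength maximum sequence length (default 512).
#' @param hiddenDim width of both fully connected layers.
#' @param poolDivisor `"tokens"` (mean over non-padding tokens, default) or
#'   `"fixed"` (divide by `maxSequenceLength`).
#' @param embeddingInit `"pretrained"` (CBOW, default) or `"random"`.
#' @param trainEmbeddings update the embedding table during training
#'   (`.pad`/`.oov` stay frozen at zero).
#' @param embeddingArgs extra arguments to [pretrainEmbeddings()].
#' @return a list with class checks applied.
#' @export
encoderConfig <- function(embeddingDim = 256L, maxSequenceLength = 512L,
                          hiddenDim = 64L,
                          poolDivisor = c("tokens", "fixed"),
                          embeddingInit = c("pretrained", "random"),
                          trainEmbeddings = FALSE,
                          embeddingArgs = list()) {
  .stopIfNot(.isCount(embeddingDim) && .isCount(maxSequenceLength) &&
               .isCount(hiddenDim), "dimensions must be positive integers")
  list(embeddingDim = as.integer(embeddingDim),
       maxSequenceLength = as.integer(maxSequenceLength),
       hiddenDim = as.integer(hiddenDim),
       poolDivisor = match.arg(poolDivisor),
       embeddingInit = match.arg(embeddingInit),
       trainEmbeddings = isTRUE(trainEmbeddings),
       embeddingArgs = embeddingArgs)
}

#' Training configuration
#'
#' @param learningRateGrid,weightDecayGrid non-empty grids searched to
#'   minimise validation loss.
#' @param maxEpochs maximum training epochs per candidate.
#' @param patience early-stopping patience in epochs without validation
#'   improvement.
#' @param batchSize minibatch size (patients).
#' @param seed integer seed governing initialisation, shuffling and (if
#'   used) embedding pretraining.
#' @return a plain list.
#' @export
trainConfig <- function(learningRateGrid = c(1e-4, 1e-3, 1e-2),
                        weightDecayGrid = c(0, 1e-5, 1e-4),
                        maxEpochs = 100L, patience = 10L, batchSize = 256L,
                        seed = 1L) {
  .stopIfNot(length(learningRateGrid) > 0L && all(learningRateGrid > 0),
             "learningRateGrid must be non-empty and positive")
  .stopIfNot(length(weightDecayGrid) > 0L && all(weightDecayGrid >= 0),
             "weightDecayGrid must be non-empty and non-negative")
  list(learningRateGrid = as.numeric(learningRateGrid),
       weightDecayGrid = as.numeric(weightDecayGrid),
       maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
       batchSize = as.integer(batchSize), seed = as.integer(seed))
}

.attrLevelsFrom <- function(p) {
  list(sex = sort(unique(p$sex)), race = sort(unique(p$race)),
       insurance = sort(unique(p$insurance)))
}

.oneHot <- function(p, attrLevels) {
  cols <- lapply(names(attrLevels), function(a) {
    lv <- attrLevels[[a]]
    m <- outer(p[[a]], lv, `==`) * 1
    colnames(m) <- paste0(a, ":", lv)
    m
  })
  do.call(cbind, cols)
}

# Ragged token layout for a cohort: embedding row per token, patient index,
# per-patient token counts. Empty sequences get one .pad (zero) token so the
# zero-vector path defines their representation.
.prepareFeatures <- function(cohort, embeddings, encoder, attrLevels) {
  p <- cohort@patients
  n <- nrow(p)
  seqs <- codeSequences(cohort)
  maxLen <- encoder$maxSequenceLength
  padRow <- match(".pad", rownames(embeddings))
  oovRow <- match(".oov", rownames(embeddings))
  rows <- lapply(seqs, function(s) {
    if (length(s) > maxLen) s <- s[(length(s) - maxLen + 1L):length(s)]
    if (length(s) == 0L) return(padRow)
    r <- match(s, rownames(embeddings))
    r[is.na(r)] <- oovRow
    r
  })
  lens <- unname(lengths(rows))
  list(tokRow = unlist(rows, use.names = FALSE),
       pid = rep.int(seq_len(n), lens),
       lens = lens,
       div = if (encoder$poolDivisor == "fixed") rep(maxLen, n) else lens,
       attr = .oneHot(p, attrLevels),
       tokIdx = split(seq_len(sum(lens)), rep.int(seq_len(n), lens)),
       n = n)
}

.subsetFeatures <- function(feat, idx) {
  tok <- unlist(feat$tokIdx[idx], use.names = FALSE)
  list(tokRow = feat$tokRow[tok],
       pid = rep.int(seq_along(idx), feat$lens[idx]),
       lens = feat$lens[idx], div = feat$div[idx],
       attr = feat$attr[idx, , drop = FALSE], n = length(idx))
}

.initParams <- function(encoder, nAttr, nOut, seed) {
  d <- encoder$embeddingDim; h <- encoder$hiddenDim
  withSeed(seed, {
    g <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)),
                                 nr, nc)
    list(W1 = g(d, h), b1 = numeric(h),
         W2 = g(h, h), b2 = numeric(h),
         W3 = g(h + nAttr, nOut), b3 = numeric(nOut))
  })
}

.forward <- function(params, embeddings, feat) {
  X <- embeddings[feat$tokRow, , drop = FALSE]
  A1 <- sweep(X %*% params$W1, 2L, params$b1, `+`)
  Z <- pmax(A1, 0)
  P <- rowsum(Z, feat$pid, reorder = TRUE) / feat$div
  dimnames(P) <- NULL
  A2 <- sweep(P %*% params$W2, 2L, params$b2, `+`)
  R <- pmax(A2, 0)
  Hin <- cbind(R, feat$attr)
  out <- sweep(Hin %*% params$W3, 2L, params$b3, `+`)
  list(X = X, A1 = A1, Z = Z, P = P, A2 = A2, Hin = Hin, out = out)
}

.backward <- function(params, fw, feat, dOut, trainEmbeddings = FALSE,
                      padRows = integer()) {
  h <- ncol(fw$P)
  dW3 <- crossprod(fw$Hin, dOut)
  db3 <- colSums(dOut)
  dHin <- dOut %*% t(params$W3)
  dA2 <- dHin[, seq_len(h), drop = FALSE] * (fw$A2 > 0)
  dW2 <- crossprod(fw$P, dA2)
  db2 <- colSums(dA2)
  dP <- dA2 %*% t(params$W2)
  dZ <- dP[feat$pid, , drop = FALSE] / feat$div[feat$pid]
  dA1 <- dZ * (fw$A1 > 0)
  dW1 <- crossprod(fw$X, dA1)
  db1 <- colSums(dA1)
  grads <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
  if (trainEmbeddings) {
    dX <- dA1 %*% t(params$W1)
    dE <- rowsum(dX, feat$tokRow, reorder = FALSE)
    rows <- as.integer(rownames(dE))
    keep <- !(rows %in% padRows)
    grads$embRows <- rows[keep]
    grads$emb <- dE[keep, , drop = FALSE]
  }
  grads
}

.adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

.adamStep <- function(params, grads, state, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  decayed <- c("W1", "W2", "W3")
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    step <- lr * mh / (sqrt(vh) + eps)
    if (nm %in% decayed) step <- step + lr * wd * params[[nm]]
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

.softmax <- function(logits) {
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}
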
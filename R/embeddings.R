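#' Pretrain medical-code embeddings (CBOW with negative sampling)
#'
#' Learns a token-to-vector table from chronological code sequences with the
#' continuous-bag-of-words objective: the mean of the context-window input
#' vectors predicts the centre token against `negative` noise tokens drawn
#' from the unigram distribution raised to the 3/4 power. Two reserved rows,
#' `.pad` and `.oov`, are appended and fixed at the zero vector.
#'
#' @param sequences list of character vectors, one chronological code
#'   sequence per patient.
#' @param dim embedding dimension (>= 1).
#' @param window one-sided context window size.
#' @param negative number of negative samples per centre token.
#' @param epochs training epochs.
#' @param learningRate SGD learning rate (linearly decayed to 10%).
#' @param maxPositions cap on centre positions processed per epoch (a random
#'   subsample when the corpus is larger); keeps pretraining fast on large
#'   simulated corpora.
#' @param center subtract the mean token vector after training (default
#'   TRUE). Word2Vec-style tables concentrate along one shared direction;
#'   removing it is standard post-processing and conditions the downstream
#'   encoder much better. `.pad`/`.oov` stay zero.
#' @param seed integer seed; deterministic given it.
#' @return numeric matrix with one named row per token plus `.pad` and
#'   `.oov` zero rows.
#' @export
pretrainEmbeddings <- function(sequences, dim = 256L, window = 5L,
                               negative = 5L, epochs = 5L,
                               learningRate = 0.05, maxPositions = 200000L,
                               center = TRUE, seed = 1L) {
  .stopIfNot(dim >= 1, "dim must be >= 1")
  sequences <- sequences[lengths(sequences) > 0L]
  .stopIfNot(length(sequences) > 0L, "corpus is empty")
  vocab <- sort(unique(unlist(sequences, use.names = FALSE)))
  .stopIfNot(length(vocab) > 0L, "empty vocabulary")
  V <- length(vocab)
  seqIdx <- lapply(sequences, function(s) match(s, vocab))

  counts <- tabulate(unlist(seqIdx, use.names = FALSE), nbins = V)
  noise <- counts^0.75
  noise <- noise / sum(noise)

  withSeed(seed, {
    Vin <- matrix(stats::runif(V * dim, -0.5 / dim, 0.5 / dim), V, dim)
    Uout <- matrix(0, V, dim)
    # flat table of (sequence, position) centre candidates
    sl <- lengths(seqIdx)
    seqOf <- rep.int(seq_along(seqIdx), sl)
    posOf <- unlist(lapply(sl, seq_len), use.names = FALSE)
    total <- length(seqOf)
    for (ep in seq_len(epochs)) {
      lr <- learningRate * (1 - 0.9 * (ep - 1) / max(epochs - 1, 1))
      use <- if (total > maxPositions)
        sample.int(total, maxPositions) else sample.int(total, total)
      negs <- sample.int(V, length(use) * negative, replace = TRUE,
                         prob = noise)
      for (k in seq_along(use)) {
        s <- seqIdx[[seqOf[use[k]]]]
        pos <- posOf[use[k]]
        ctx <- s[max(1L, pos - window):min(length(s), pos + window)]
        ctx <- ctx[-(pos - max(1L, pos - window) + 1L)]
        if (length(ctx) == 0L) next
        vbar <- colMeans(Vin[ctx, , drop = FALSE])
        neg <- negs[((k - 1L) * negative + 1L):(k * negative)]
        neg <- neg[neg != s[pos]] # the true centre is never a negative
        targets <- c(s[pos], neg)
        labels <- c(1, numeric(length(neg)))
        sc <- 1 / (1 + exp(-(Uout[targets, , drop = FALSE] %*% vbar)))
        g <- lr * (labels - as.numeric(sc))
        dv <- crossprod(Uout[targets, , drop = FALSE], g)
        Uout[targets, ] <- Uout[targets, , drop = FALSE] + outer(g, vbar)
        Vin[ctx, ] <- Vin[ctx, , drop = FALSE] +
          matrix(dv / length(ctx), length(ctx), dim, byrow = TRUE)
      }
    }
    if (center) Vin <- sweep(Vin, 2L, colMeans(Vin))
    emb <- rbind(Vin, matrix(0, 2L, dim))
    rownames(emb) <- c(vocab, ".pad", ".oov")
    emb
  })
}

#' Random frozen embedding table
#'
#' Alternative to [pretrainEmbeddings()] for small synthetic vocabularies:
#' i.i.d. Gaussian token vectors with `.pad` and `.oov` zero rows.
#'
#' @param vocab character vector of tokens.
#' @param dim embedding dimension.
#' @param seed integer seed.
#' @param sd standard deviation of the entries.
#' @return embedding matrix as in [pretrainEmbeddings()].
#' @export
randomEmbeddings <- function(vocab, dim, seed = 1L, sd = 0.3) {
  withSeed(seed, {
    emb <- rbind(matrix(stats::rnorm(length(vocab) * dim, sd = sd),
                        length(vocab), dim),
                 matrix(0, 2L, dim))
    rownames(emb) <- c(vocab, ".pad", ".oov")
    emb
  })
}

#' Per-patient chronological code sequences
#'
#' @param cohort a [PatientCohort].
#' @return named list of character vectors, one per patient (empty vectors
#'   for patients without codes), in `patients(cohort)` order.
#' @export
codeSequences <- function(cohort) {
  p <- cohort@patients
  cds <- cohort@codes
  out <- rep(list(character()), nrow(p))
  names(out) <- p$patient_id
  if (nrow(cds)) {
    cds <- cds[order(match(cds$patient_id, p$patient_id), cds$age), ]
    sp <- split(cds$code, factor(cds$patient_id, levels = p$patient_id))
    out[names(sp)] <- sp
  }
  out
}
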
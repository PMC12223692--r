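ns <- asNamespace("horizonTTE")

encodeRep <- function(co, emb, enc) {
  feat <- ns$.prepareFeatures(co, emb, enc,
                              ns$.attrLevelsFrom(co@patients))
  params <- ns$.initParams(enc, ncol(feat$attr), 1L, seed = 9)
  fw <- ns$.forward(params, emb, feat)
  list(R = fw$Hin, params = params, feat = feat)
}

test_that("mean pooling makes the representation order-invariant", {
  emb <- randomEmbeddings(letters[1:6], 5, seed = 1)
  enc <- tinyEncoder(embeddingDim = 5)
  codesA <- data.frame(patient_id = rep(c("p0001", "p0002"), each = 3),
                       age = c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3),
                       code = c("a", "b", "c", "c", "a", "b"),
                       stringsAsFactors = FALSE)
  co <- makeCohort(times = c(2, 2), events = c(0, 0), codes = codesA,
                   sex = c("male", "male"))
  out <- encodeRep(co, emb, enc)
  expect_equal(out$R[1, ], out$R[2, ], tolerance = 1e-12)
})

test_that("long sequences keep only the most recent events", {
  emb <- randomEmbeddings(c("old", "new"), 4, seed = 2)
  enc <- tinyEncoder(embeddingDim = 4, maxSequenceLength = 3L)
  # 5 events: two old then three new; only the 3 most recent survive
  codes <- data.frame(patient_id = rep("p0001", 5),
                      age = c(0.1, 0.2, 0.5, 0.6, 0.7),
                      code = c("old", "old", "new", "new", "new"),
                      stringsAsFactors = FALSE)
  co <- makeCohort(times = 2, events = 0, codes = codes)
  feat <- ns$.prepareFeatures(co, emb, enc, ns$.attrLevelsFrom(co@patients))
  expect_equal(feat$lens, 3L)
  expect_equal(unique(rownames(emb)[feat$tokRow]), "new")
})

test_that("an empty sequence equals a single padding token", {
  emb <- randomEmbeddings("a", 4, seed = 3)
  enc <- tinyEncoder(embeddingDim = 4)
  codesPad <- data.frame(patient_id = character(), age = numeric(),
                         code = character(), stringsAsFactors = FALSE)
  co <- makeCohort(times = c(2, 2), events = c(0, 0), codes = codesPad,
                   sex = c("male", "male"))
  out <- encodeRep(co, emb, enc)
  # both patients empty: identical constant representation through the
  # zero-vector path (relu(b1) pooled and mapped on)
  expect_equal(out$R[1, ], out$R[2, ], tolerance = 1e-12)
  # and it matches tracing relu(b1) through the second layer by hand
  p <- out$params
  h1 <- pmax(p$b1, 0)
  h2 <- pmax(as.numeric(h1 %*% p$W2) + p$b2, 0)
  expect_equal(unname(out$R[1, seq_along(h2)]), h2, tolerance = 1e-12)
})

test_that("unknown codes map to the zero out-of-vocabulary vector", {
  emb <- randomEmbeddings("known", 4, seed = 4)
  enc <- tinyEncoder(embeddingDim = 4)
  codes <- data.frame(patient_id = "p0001", age = 0.5, code = "mystery",
                      stringsAsFactors = FALSE)
  co <- makeCohort(times = 2, events = 0, codes = codes)
  feat <- ns$.prepareFeatures(co, emb, enc, ns$.attrLevelsFrom(co@patients))
  expect_equal(rownames(emb)[feat$tokRow], ".oov")
})

test_that("the fixed-length pool divisor is honoured", {
  emb <- randomEmbeddings("a", 4, seed = 5)
  encTok <- tinyEncoder(embeddingDim = 4, maxSequenceLength = 8L)
  encFix <- encoderConfig(embeddingDim = 4, maxSequenceLength = 8L,
                          hiddenDim = 8L, poolDivisor = "fixed",
                          embeddingInit = "random")
  codes <- data.frame(patient_id = rep("p0001", 2), age = c(0.1, 0.2),
                      code = c("a", "a"), stringsAsFactors = FALSE)
  co <- makeCohort(times = 2, events = 0, codes = codes)
  al <- ns$.attrLevelsFrom(co@patients)
  fTok <- ns$.prepareFeatures(co, emb, encTok, al)
  fFix <- ns$.prepareFeatures(co, emb, encFix, al)
  expect_equal(fTok$div, 2L)
  expect_equal(fFix$div, 8L)
})

test_that("the DTNN head is a softmax over bins plus beyond-horizon", {
  grid <- timeGrid(1:4)
  co <- generateCohort(cohortConfig(40, baselineHazards = rep(0.1, 4),
                                    seed = 6))
  emb <- randomEmbeddings(sort(unique(codeEvents(co)$code)), 8, seed = 7)
  enc <- tinyEncoder()
  feat <- ns$.prepareFeatures(co, emb, enc, ns$.attrLevelsFrom(co@patients))
  params <- ns$.initParams(enc, ncol(feat$attr), nBins(grid) + 1L, seed = 8)
  fw <- ns$.forward(params, emb, feat)
  probs <- ns$.softmax(fw$out)
  expect_equal(ncol(probs), nBins(grid) + 1L)
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-9)
  # zero head weights give the uniform distribution
  params$W3[] <- 0; params$b3[] <- 0
  fw0 <- ns$.forward(params, emb, feat)
  expect_equal(unique(as.numeric(ns$.softmax(fw0$out))), 1 / 5,
               tolerance = 1e-12)
})
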
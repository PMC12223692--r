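# Build a PatientCohort directly from outcome vectors (for metric and filter
# tests that do not need the generator).
makeCohort <- function(times, events, birthYears = NULL, codes = NULL,
                       eventTimes = NULL, censorTimes = NULL, sex = NULL) {
  n <- length(times)
  if (is.null(birthYears)) birthYears <- rep(2016L, n)
  if (is.null(eventTimes))
    eventTimes <- ifelse(events == 1, times, Inf)
  if (is.null(censorTimes))
    censorTimes <- ifelse(events == 1, times + 1, times)
  if (is.null(sex)) sex <- rep(c("male", "female"), length.out = n)
  p <- data.frame(
    patient_id = sprintf("p%04d", seq_len(n)),
    birth_year = as.integer(birthYears),
    sex = sex,
    race = rep("A", n), insurance = rep("public", n),
    event_time = eventTimes, censoring_time = censorTimes,
    time = times, event = as.integer(events), stringsAsFactors = FALSE)
  if (is.null(codes))
    codes <- data.frame(patient_id = character(), age = numeric(),
                        code = character(), stringsAsFactors = FALSE)
  new("PatientCohort", patients = p, codes = codes, metadata = list())
}

# small fast training configuration shared by the training unit tests
tinyTrainConfig <- function(...) {
  args <- list(learningRateGrid = 0.01, weightDecayGrid = 0,
               maxEpochs = 4L, patience = 2L, batchSize = 128L, seed = 1L)
  args[names(list(...))] <- list(...)
  do.call(trainConfig, args)
}

tinyEncoder <- function(...) {
  args <- list(embeddingDim = 8L, maxSequenceLength = 16L, hiddenDim = 8L,
               embeddingInit = "random")
  args[names(list(...))] <- list(...)
  do.call(encoderConfig, args)
}
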
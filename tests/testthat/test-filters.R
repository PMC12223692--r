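test_that("the prediction-age cutoff removes early-diagnosed and early-censored children", {
  co <- makeCohort(times = c(0.1, 2, 6, 7), events = c(0, 1, 0, 1))
  out <- applyFilter(co, filterSpec(0.25))
  expect_equal(nPatients(out), 3)
  expect_false("p0001" %in% patients(out)$patient_id)
})

test_that("the follow-up criterion keeps early events by default", {
  co <- makeCohort(times = c(2, 6), events = c(0, 0))
  out <- applyFilter(co, filterSpec(0.25, minFollowupYears = 5))
  expect_equal(patients(out)$time, 6)

  # an observed event before the threshold is retained by default ...
  co2 <- makeCohort(times = c(2, 6), events = c(1, 0))
  out2 <- applyFilter(co2, filterSpec(0.25, minFollowupYears = 5))
  expect_equal(nPatients(out2), 2)
  # ... and removed under the aggressive semantics
  out3 <- applyFilter(co2, filterSpec(0.25, minFollowupYears = 5,
                                      dropEarlyEvents = TRUE))
  expect_equal(patients(out3)$time, 6)
})

test_that("the birth-year cutoff filters by year of birth", {
  co <- makeCohort(times = rep(5, 3), events = rep(0, 3),
                   birthYears = c(2017L, 2019L, 2020L))
  out <- applyFilter(co, filterSpec(0.25, yobMax = 2018L))
  expect_equal(nPatients(out), 1)
  expect_equal(patients(out)$birth_year, 2017L)
})

test_that("filtering is idempotent and leaves the input unmodified", {
  co <- generateCohort(cohortConfig(500, seed = 12))
  before <- patients(co)
  fs <- filterSpec(1, yobMax = 2019L, minFollowupYears = 3)
  once <- applyFilter(co, fs)
  twice <- applyFilter(once, fs)
  expect_identical(patients(once), patients(twice))
  expect_identical(patients(co), before)
  expect_error(applyFilter(co, filterSpec(100)), "every patient")
})

test_that("feature truncation respects the cutoff and the diagnosis time", {
  codes <- data.frame(patient_id = rep("p0001", 3),
                      age = c(0.1, 0.2, 1.4), code = c("a", "b", "c"),
                      stringsAsFactors = FALSE)
  co <- makeCohort(times = 2, events = 1, codes = codes)
  out <- truncateFeatures(co, 0.25)
  expect_equal(nrow(codeEvents(out)), 2)

  # leakage rule: codes at or after the diagnosis age are dropped even when
  # they precede the cutoff (raw post-diagnosis codes set via the slots, as
  # they would appear in unprocessed EHR extracts)
  codes2 <- data.frame(patient_id = rep("p0001", 2), age = c(0.1, 1.2),
                       code = c("a", "b"), stringsAsFactors = FALSE)
  co2 <- makeCohort(times = 2, events = 1, codes = codes2,
                    eventTimes = 2, censorTimes = 3)
  co2@patients$event_time <- 1.15
  co2@patients$time <- 1.15
  out2 <- truncateFeatures(co2, 1.25)
  expect_equal(codeEvents(out2)$age, 0.1)

  co3 <- makeCohort(times = 2, events = 0)
  out3 <- truncateFeatures(co3, 1.25)
  expect_equal(nrow(codeEvents(out3)), 0)
  expect_identical(patients(out3), patients(co3))
})

test_that("semisynthetic censoring rescales to the target maximum exactly", {
  co <- makeCohort(times = c(2, 4, 6), events = c(0, 0, 0))
  out <- applySemisyntheticCensoring(co, 1.2)
  expect_equal(patients(out)$censoring_time, c(0.4, 0.8, 1.2))

  # event before the new censoring time stays an event
  co2 <- makeCohort(times = c(0.3, 6), events = c(1, 0),
                    eventTimes = c(0.3, Inf), censorTimes = c(6, 6))
  out2 <- applySemisyntheticCensoring(co2, 1.2)
  expect_equal(patients(out2)$event[1], 1L)
  expect_equal(patients(out2)$time[1], 0.3)

  # event overtaken by the new censoring time becomes censored
  co3 <- makeCohort(times = c(2, 6), events = c(1, 0),
                    eventTimes = c(2, Inf), censorTimes = c(6, 6))
  out3 <- applySemisyntheticCensoring(co3, 1.2)
  expect_equal(patients(out3)$event[1], 0L)
  expect_equal(patients(out3)$time[1], 1.2)
})

test_that("semisynthetic censoring preserves latent event times and loses events monotonically", {
  co <- generateCohort(cohortConfig(2000, baselineHazards = rep(0.05, 8),
                                    seed = 17))
  out <- applySemisyntheticCensoring(co, 1.2)
  expect_identical(patients(out)$event_time, patients(co)$event_time)
  expect_lte(sum(patients(out)$event), sum(patients(co)$event))
  expect_equal(max(patients(out)$censoring_time), 1.2)
  # cohort invariants still hold (validity runs in the constructor)
  expect_true(validObject(out))
})
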
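test_that("generated cohorts satisfy the survival invariants", {
  cfg <- cohortConfig(10000, seed = 11)
  co <- generateCohort(cfg)
  p <- patients(co)
  expect_equal(nrow(p), 10000)
  expect_identical(p$event, as.integer(p$event_time <= p$censoring_time))
  expect_equal(p$time, pmin(p$event_time, p$censoring_time))
  expect_true(all(p$censoring_time > 0))
  expect_true(all(p$event_time > 0))
  expect_true(all(p$time[p$event == 1] == p$event_time[p$event == 1]))
  cds <- codeEvents(co)
  tt <- p$time[match(cds$patient_id, p$patient_id)]
  expect_true(all(cds$age < tt))
})

test_that("zero baseline hazard yields no events at all", {
  cfg <- cohortConfig(500, baselineHazards = rep(0, 8), seed = 3)
  p <- patients(generateCohort(cfg))
  expect_true(all(p$event == 0L))
  expect_true(all(is.infinite(p$event_time)))
})

test_that("with no dropout, censoring equals the administrative age", {
  cfg <- cohortConfig(500, dropoutRate = 0, birthYearRange = c(2014L, 2016L),
                      seed = 4)
  p <- patients(generateCohort(cfg))
  # admin censoring is extraction - (birth year + within-year offset)
  off <- cfg@extractionYear - p$birth_year - p$censoring_time
  expect_true(all(off > 0 & off < 1))
})

test_that("empirical incidence matches the closed-form geometric curve", {
  h <- 0.1
  cfg <- cohortConfig(50000, baselineHazards = rep(h, 8),
                      birthYearRange = c(2010L, 2014L), dropoutRate = 0,
                      covariateEffects = NULL, prevalenceTrend = 0,
                      riskEffect = 0, meanCodesPerYear = 1, seed = 21)
  p <- patients(generateCohort(cfg))
  for (k in 1:8) {
    expected <- 1 - (1 - h)^k
    observed <- mean(p$event_time <= k)
    se <- sqrt(expected * (1 - expected) / nrow(p))
    expect_lt(abs(observed - expected), max(0.01, 3 * se))
  }
})

test_that("the generator is deterministic given the seed", {
  cfg <- cohortConfig(300, seed = 99)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(patients(a), patients(b))
  expect_identical(codeEvents(a), codeEvents(b))
  c2 <- generateCohort(cohortConfig(300, seed = 100))
  expect_false(identical(patients(a), patients(c2)))
})

test_that("invalid configurations are rejected", {
  expect_error(cohortConfig(100, baselineHazards = c(0.1, 1.0)), "0, 1")
  expect_error(cohortConfig(100, birthYearRange = c(2020L, 2020L)),
               "nondegenerate")
  expect_error(cohortConfig(0), "nPatients")
  expect_error(cohortConfig(100, dropoutRate = -1), "dropoutRate")
})

test_that("the immune fraction adds never-event children", {
  base <- cohortConfig(4000, baselineHazards = rep(0.3, 8),
                       birthYearRange = c(2010L, 2014L), riskEffect = 0,
                       covariateEffects = NULL, seed = 5)
  imm <- cohortConfig(4000, baselineHazards = rep(0.3, 8),
                      birthYearRange = c(2010L, 2014L), riskEffect = 0,
                      covariateEffects = NULL, immuneFraction = 0.5, seed = 5)
  fracNever <- function(cfg) mean(is.infinite(patients(generateCohort(cfg))$event_time))
  expect_gt(fracNever(imm), fracNever(base) + 0.3)
})

test_that("cohorts round-trip through CSV files", {
  co <- generateCohort(cohortConfig(150, seed = 8))
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  back <- readCohort(dir)
  expect_equal(patients(back), patients(co))
  expect_equal(codeEvents(back), codeEvents(co))
})

test_that("cohort configuration files are parsed and validated", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "nPatients: 50",
    "baselineHazards: [0.05, 0.05]",
    "birthYearRange: [2014, 2020]",
    "covariateEffects:",
    "  'sex:male': 0.4",
    "seed: 7"), path)
  cfg <- readCohortConfig(path)
  expect_s4_class(cfg, "CohortConfig")
  expect_equal(cfg@covariateEffects, c("sex:male" = 0.4))
  writeLines(c("nPatients: 10", "bogusKey: 1"), path)
  expect_error(readCohortConfig(path), "bogusKey")
})

test_that("risk codes are enriched in children with events", {
  cfg <- cohortConfig(4000, baselineHazards = rep(0.05, 8),
                      birthYearRange = c(2010L, 2014L), riskEffect = 1,
                      riskEnrichment = 1.5, seed = 31)
  co <- generateCohort(cfg)
  p <- patients(co)
  cds <- codeEvents(co)
  nRisk <- round(cfg@vocabularySize * cfg@riskCodeFraction)
  riskTokens <- sprintf("c%04d", seq_len(nRisk))
  frac <- tapply(cds$code %in% riskTokens, cds$patient_id, mean)
  frac <- frac[match(p$patient_id, names(frac))]
  expect_gt(mean(frac[p$event == 1], na.rm = TRUE),
            mean(frac[p$event == 0], na.rm = TRUE))
})
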
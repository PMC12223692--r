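test_that("time-varying AUC separates cases from controls and excludes the censored", {
  expect_equal(aucT(c(0.9, 0.8, 0.2, 0.1), c(1, 2, 5, 5), c(1, 1, 0, 0), 3), 1)
  expect_equal(aucT(rep(0.5, 4), c(1, 2, 5, 5), c(1, 1, 0, 0), 3), 0.5)
  # censored before t are excluded: their score cannot affect the value
  sc <- c(0.9, 0.1, 0.99)
  expect_equal(aucT(sc, c(1, 5, 2), c(1, 0, 0), 3),
               aucT(sc[1:2], c(1, 5), c(1, 0), 3))
  expect_error(aucT(c(1, 2), c(5, 6), c(0, 0), 3), "no cases")
  expect_error(aucT(c(1, 2), c(1, 2), c(1, 1), 3), "no controls")
})

test_that("time-varying AP reproduces precision-at-case-ranks", {
  # perfect ranking: 2 cases above 2 controls
  expect_equal(apT(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 9, 9), c(1, 1, 0, 0), 5), 1)
  # worst ranking: single case below 3 controls -> precision 1/4
  expect_equal(apT(c(0.1, 0.5, 0.6, 0.7), c(1, 9, 9, 9), c(1, 0, 0, 0), 5),
               0.25)
})

test_that("regular AUC/AP treat censored children as negatives", {
  expect_equal(regularAuc(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(regularAuc(rep(0.3, 4), c(1, 1, 0, 0)), 0.5)
  expect_equal(regularAp(c(0.9, 0.8, 0.1), c(1, 0, 0)), 1)
  expect_error(regularAuc(c(1, 2), c(1, 1)), "both classes")
})

test_that("early censoring of future cases inflates regular AUC relative to AUC_t", {
  # six children; one true future case is censored at age 1, before its
  # diagnosis, and a censoring-driven classifier scores it LOW (0.05)
  scores <- c(0.95, 0.9, 0.05, 0.3, 0.2, 0.1)
  latentE <- c(2, 2.5, 3, Inf, Inf, Inf)
  cens <- c(9, 9, 1, 9, 9, 9)
  times <- pmin(latentE, cens)
  events <- as.integer(latentE <= cens)
  # on observed labels the mistake is rewarded: perfect regular AUC
  aucObserved <- regularAuc(scores, events)
  # against the latent truth (no censoring) the same scores are penalised
  aucLatent <- aucT(scores, latentE, as.integer(latentE < Inf), 5)
  expect_equal(aucObserved, 1)
  expect_gt(aucObserved, aucLatent)
  # AUC_t on the censored data excludes the unknowable child instead of
  # rewarding the mistake
  expect_equal(aucT(scores, times, events, 5), 1)
})

test_that("Harrell's concordance orders comparable pairs", {
  expect_equal(harrellC(c(3, 2, 1), c(1, 2, 3), c(1, 1, 0)), 1)
  expect_equal(harrellC(c(1, 2, 3), c(1, 2, 3), c(1, 1, 0)), 0)
  expect_error(harrellC(1, 5, 0), "no comparable pairs")
})

test_that("metric implementations agree with brute-force oracles on random instances", {
  set.seed(41)
  for (r in 1:50) {
    n <- sample(10:80, 1)
    inst <- randomInstance(n, tie = r %% 3 == 0)
    t <- stats::median(inst$times)
    ok <- any(inst$events == 1 & inst$times <= t) && any(inst$times > t)
    if (ok) {
      expect_equal(aucT(inst$scores, inst$times, inst$events, t),
                   bfAucT(inst$scores, inst$times, inst$events, t),
                   tolerance = 1e-12)
      expect_equal(apT(inst$scores, inst$times, inst$events, t),
                   bfApT(inst$scores, inst$times, inst$events, t),
                   tolerance = 1e-12)
    }
    expect_equal(harrellC(inst$scores, inst$times, inst$events),
                 bfHarrellC(inst$scores, inst$times, inst$events),
                 tolerance = 1e-12)
    if (sum(inst$events == 0) >= 2)
      expect_equal(censoringConcordance(inst$scores, inst$times, inst$events),
                   bfCensoringConcordance(inst$scores, inst$times,
                                          inst$events),
                   tolerance = 1e-12)
  }
})

test_that("concordance agrees with survival::concordance on tie-free data", {
  set.seed(13)
  n <- 80
  sc <- rnorm(n); tt <- rexp(n) + 0.01; ev <- rbinom(n, 1, 0.6)
  ours <- harrellC(sc, tt, ev)
  ref <- survival::concordance(survival::Surv(tt, ev) ~ sc,
                               reverse = TRUE)$concordance
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("censoring concordance is the all-events reduction on the censored subset", {
  set.seed(14)
  n <- 50
  sc <- runif(n); tt <- rexp(n) + 0.1; ev <- rbinom(n, 1, 0.5)
  cen <- ev == 0
  expect_equal(censoringConcordance(sc, tt, ev),
               harrellC(sc[cen], tt[cen], rep(1, sum(cen))))
  # independent scores give a null value near 0.5 at large n
  m <- 4000
  expect_lt(abs(censoringConcordance(runif(m), rexp(m) + 0.1,
                                     rep(0, m)) - 0.5), 0.03)
  expect_error(censoringConcordance(c(1, 2), c(1, 2), c(1, 1)),
               "two censored")
})

test_that("rank-invariance: AUC_t and Harrell's C only use score order", {
  set.seed(15)
  inst <- randomInstance(60)
  t <- stats::median(inst$times)
  mono <- function(x) exp(3 * x) + 1
  expect_equal(aucT(inst$scores, inst$times, inst$events, t),
               aucT(mono(inst$scores), inst$times, inst$events, t))
  expect_equal(harrellC(inst$scores, inst$times, inst$events),
               harrellC(mono(inst$scores), inst$times, inst$events))
})

test_that("Kaplan-Meier matches the hand-computed product limit", {
  km <- kmEstimate(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(kmSurvivalAt(km, 1), 0.75)        # 3/4
  expect_equal(kmSurvivalAt(km, 3), 0.375)       # (3/4) * (1/2)
  expect_equal(kmSurvivalAt(km, 0.5), 1)
  # no events: flat at 1
  km2 <- kmEstimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(kmSurvivalAt(km2, c(1, 2, 3)) == 1))
  # no censoring: complement of the ECDF
  tt <- c(0.5, 1.2, 2.5, 3.1, 4)
  km3 <- kmEstimate(tt, rep(1, 5))
  for (t in c(0.4, 1, 2.5, 5))
    expect_equal(kmSurvivalAt(km3, t), mean(tt > t))
})

test_that("calibration with constant predictions collapses to the cohort KM incidence", {
  set.seed(16)
  tt <- rexp(200) + 0.1; ev <- rbinom(200, 1, 0.5)
  cc <- calibrationCurve(rep(0.3, 200), tt, ev, t = 1)
  expect_equal(nrow(cc), 1)
  km <- kmEstimate(tt, ev)
  expect_equal(cc$observedIncidence, 1 - kmSurvivalAt(km, 1))
})

test_that("calibration points sit on the diagonal when predictions equal true incidence", {
  # geometric event times: true incidence by t=3 is 1-(1-h)^3, with h
  # varying by group; no censoring
  set.seed(17)
  n <- 20000
  h <- runif(n, 0.05, 0.4)
  E <- rgeom(n, h) + 1 # yearly bins, end-of-bin convention
  pred <- 1 - (1 - h)^3
  cc <- calibrationCurve(pred, E, rep(1, n), t = 3.5)
  for (i in seq_len(nrow(cc))) {
    se <- max(cc$observedSE[i], 1 / cc$n[i])
    expect_lt(abs(cc$meanPredicted[i] - cc$observedIncidence[i]), 3 * se)
  }
})

test_that("bootstrap intervals behave as expected", {
  # constant metric: zero-width interval
  est <- bootstrapCi(function(idx) 0.7, n = 50, nBoot = 30, seed = 2,
                     metricName = "const")
  expect_equal(est$ci_low, 0.7)
  expect_equal(est$ci_high, 0.7)
  expect_equal(est$point, 0.7)

  set.seed(3)
  x <- rnorm(200)
  est2 <- bootstrapCi(function(idx) mean(x[idx]), n = 200, nBoot = 100,
                      seed = 4, metricName = "mean")
  expect_lte(est2$ci_low, est2$point)
  expect_gte(est2$ci_high, est2$point)
  # deterministic given seed
  est3 <- bootstrapCi(function(idx) mean(x[idx]), n = 200, nBoot = 100,
                      seed = 4, metricName = "mean")
  expect_identical(est2$ci_low, est3$ci_low)
})

test_that("bootstrap CI for the mean covers the truth at about the nominal rate", {
  set.seed(18)
  cover <- 0
  for (r in 1:100) {
    x <- rnorm(80, mean = 1)
    est <- bootstrapCi(function(idx) mean(x[idx]), n = 80, nBoot = 100,
                       seed = r)
    cover <- cover + (est$ci_low <= 1 && 1 <= est$ci_high)
  }
  expect_gte(cover, 85)
})
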
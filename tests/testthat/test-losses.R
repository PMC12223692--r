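test_that("the discrete-time likelihood reproduces hand-computed values", {
  probs <- c(0.2, 0.3, 0.5) # 2 bins + beyond-horizon
  expect_equal(dtnnLoss(probs, tBin = 2, s = 1), -log(0.3))
  expect_equal(dtnnLoss(probs, tBin = 1, s = 0), -log(0.8))
  expect_equal(dtnnLoss(c(0, 1, 0), tBin = 2, s = 1), 0)
  expect_error(dtnnLoss(probs, tBin = 3, s = 1), "out of range")
  expect_error(dtnnLoss(probs, tBin = 0, s = 1), "out of range")
  # clamped, not infinite, on degenerate mass
  expect_lt(dtnnLoss(c(1, 0, 0), tBin = 2, s = 1), -log(1e-13))
})

test_that("with no censoring the DTNN loss is the categorical NLL, gradients included", {
  set.seed(5)
  n <- 16; K <- 4
  logits <- matrix(rnorm(n * (K + 1)), n)
  tBin <- sample(K, n, replace = TRUE)
  s <- rep(1L, n)
  lg <- horizonTTE:::.dtnnLossGrad(logits, tBin, s)
  probs <- horizonTTE:::.softmax(logits)
  nll <- -mean(log(probs[cbind(seq_len(n), tBin)]))
  expect_equal(lg$loss, nll)
  # categorical cross-entropy gradient: (p - onehot)/n
  gref <- probs
  gref[cbind(seq_len(n), tBin)] <- gref[cbind(seq_len(n), tBin)] - 1
  expect_equal(lg$dOut, gref / n, tolerance = 1e-12)
})

test_that("the BC head is logistic with binary cross-entropy", {
  expect_equal(stats::plogis(0), 0.5)
  expect_equal(bceLoss(0.5, 1), log(2))
  expect_equal(bceLoss(0.5, 0), log(2))
  expect_equal(bceLoss(0.9, 1), -log(0.9))
})

test_that("the Cox negative partial log-likelihood matches hand computation and is shift-invariant", {
  # two events at times 1 < 2, both log-hazards 0: risk sets {1,2} then {2}
  expect_equal(coxPartialLoglik(c(0, 0), c(1, 2), c(1, 1)), log(2))
  lp <- c(0.3, -0.2, 1.1, 0)
  tt <- c(1, 2, 3, 4); ev <- c(1, 0, 1, 1)
  expect_equal(coxPartialLoglik(lp, tt, ev),
               coxPartialLoglik(lp + 10, tt, ev), tolerance = 1e-8)
  # perfect ranking limit: event patient dominates every later patient
  expect_lt(coxPartialLoglik(c(30, 0, 0), c(1, 5, 6), c(1, 0, 0)), 1e-8)
  expect_error(coxPartialLoglik(c(0, 0), c(1, 2), c(0, 0)), "undefined")
})

test_that("the Cox loss agrees with explicit risk-set enumeration, ties included", {
  set.seed(31)
  for (r in 1:100) {
    n <- sample(5:30, 1)
    inst <- randomInstance(n, tie = r %% 2 == 0)
    if (!any(inst$events == 1)) next
    expect_equal(coxPartialLoglik(inst$scores, inst$times, inst$events),
                 bfCoxNegPLL(inst$scores, inst$times, inst$events),
                 tolerance = 1e-12)
  }
})

test_that("the Cox loss matches survival::coxph at its fitted coefficient", {
  set.seed(8)
  n <- 60
  x <- rnorm(n)
  tt <- rexp(n, exp(0.5 * x)) + 1e-3
  ev <- rbinom(n, 1, 0.8)
  fit <- survival::coxph(survival::Surv(tt, ev) ~ x, ties = "breslow")
  expect_equal(coxPartialLoglik(fit$coefficients * x, tt, ev),
               -fit$loglik[2], tolerance = 1e-8)
})

test_that("deep Cox event probabilities follow the Breslow baseline", {
  # single event among two at t=1, both lp=0: increment = 1/2
  bl <- breslowBaseline(c(0, 0), c(1, 2), c(1, 0))
  expect_equal(bl$times, 1)
  expect_equal(bl$cumhaz, 0.5)
  bl2 <- list(times = 1, cumhaz = 0.1)
  expect_equal(dcphSurvival(0, bl2, 1), 1 - exp(-0.1))
  # flat extrapolation beyond the last baseline time
  expect_equal(dcphSurvival(0, bl2, 50), 1 - exp(-0.1))
  # before the first event time no hazard has accrued
  expect_equal(dcphSurvival(0, bl2, 0.5), 0)
  # ordering preserved and zero-hazard limit
  expect_true(dcphSurvival(1, bl2, 1) > dcphSurvival(-1, bl2, 1))
  expect_lt(dcphSurvival(-30, bl2, 1), 1e-12)
})
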
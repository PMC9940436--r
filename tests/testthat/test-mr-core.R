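test_that("Wald ratio arithmetic, sign, and error behaviour", {
  e <- waldRatio(0.5, 0.1, 0.1)
  expect_equal(effectSize(e), 0.2)
  expect_equal(stdError(e), 0.2)
  eNeg <- waldRatio(-0.5, 0.1, 0.1)
  expect_equal(effectSize(eNeg), -0.2)
  expect_equal(stdError(eNeg), 0.2)
  expect_error(waldRatio(0, 0.1, 0.1), "undefined")
})

test_that("first-order Wald SE is adequate for strong instruments", {
  # Monte-Carlo ratio-distribution oracle: with betaX = 0.5 known to
  # seX = 0.01, the true sd of the ratio differs from the first-order SE
  # by well under 1%, justifying the first-order default
  withSeed(101, {
    n <- 1e5
    num <- rnorm(n, 0.1, 0.1)
    den <- rnorm(n, 0.5, 0.01)
    mcSd <- sd(num / den)
  })
  first <- stdError(waldRatio(0.5, 0.1, 0.1))
  second <- stdError(waldRatio(0.5, 0.1, 0.1, seExposure = 0.01,
                               secondOrder = TRUE))
  expect_lt(abs(first - mcSd) / mcSd, 0.01)
  expect_lt(abs(second - first) / first, 0.01)
})

test_that("IVW reproduces closed-form values and the auto-mode rule", {
  h1 <- makeHset(0.5, 0.1, 0.1)
  expect_equal(effectSize(mrIVW(h1)), effectSize(waldRatio(0.5, 0.1, 0.1)))
  expect_equal(stdError(mrIVW(h1)), 0.2)

  h3 <- makeHset(c(0.5, 0.4, 0.25), c(0.05, 0.06, 0.02), rep(0.1, 3))
  e3 <- mrIVW(h3)
  expect_equal(methodTag(e3), "ivw_fixed")   # k = 3 -> auto picks fixed
  expect_equal(effectSize(e3), 0.11429, tolerance = 1e-4)
  expect_equal(stdError(e3), 0.14548, tolerance = 1e-4)
  # independent weighted-least-squares oracle (origin regression)
  lmfit <- lm(c(0.05, 0.06, 0.02) ~ 0 + c(0.5, 0.4, 0.25),
              weights = rep(100, 3))
  expect_equal(effectSize(e3), unname(coef(lmfit)), tolerance = 1e-10)

  h4 <- makeHset(rep(1, 4), c(0, 0.2, 0.1, 0.3), rep(0.1, 4))
  expect_equal(effectSize(mrIVW(h4)), 0.15)
  expect_equal(stdError(mrIVW(h4, "fixed")), 0.05)
  expect_equal(stdError(mrIVW(h4, "random")), 0.06455, tolerance = 1e-4)
  expect_equal(methodTag(mrIVW(h4)), "ivw_random")
  h0 <- makeHset(0.5, 0.1, 0.1)
  h0@data <- h0@data[0, ]
  expect_error(mrIVW(h0), "at least 1")
})

test_that("Cochran's Q matches the chi-square reference", {
  hSame <- makeHset(c(1, 2, 4), c(0.1, 0.2, 0.4), rep(0.1, 3))
  q0 <- cochranQ(hSame)
  expect_equal(q0@Q, 0)
  expect_equal(pValue(q0), 1)

  h4 <- makeHset(rep(1, 4), c(0, 0.2, 0.1, 0.3), rep(0.1, 4))
  q <- cochranQ(h4)
  expect_equal(q@Q, 5)
  expect_equal(q@df, 3)
  expect_equal(pValue(q), 0.1718, tolerance = 1e-4)
  expect_equal(pValue(q), pchisq(5, 3, lower.tail = FALSE))

  # Q is invariant to jointly rescaling outcome betas and SEs
  h4c <- makeHset(rep(1, 4), 3 * c(0, 0.2, 0.1, 0.3), rep(0.3, 4))
  expect_equal(cochranQ(h4c)@Q, q@Q)
  expect_error(cochranQ(makeHset(1, 0.1, 0.1)), "at least 2")
})

test_that("random-effects IVW never undercuts the fixed-effects SE", {
  for (s in 1:20) {
    set.seed(s)
    k <- sample(4:12, 1)
    h <- makeHset(runif(k, 0.1, 0.5), rnorm(k, 0.05, 0.05),
                  runif(k, 0.05, 0.2))
    seF <- stdError(mrIVW(h, "fixed"))
    seR <- stdError(mrIVW(h, "random"))
    Q <- cochranQ(h)@Q
    expect_gte(seR, seF)
    if (Q <= k - 1) expect_equal(seR, seF)
    else expect_gt(seR, seF)
  }
})

test_that("MR-Egger fits exactly and matches the normal-equations oracle", {
  bx <- c(0.2, 0.5, 0.9, 1.4)
  hExact <- makeHset(bx, 0.1 * bx, rep(0.05, 4))
  eg <- mrEgger(hExact)
  expect_equal(effectSize(eg@slope), 0.1, tolerance = 1e-12)
  expect_equal(eg@intercept, 0, tolerance = 1e-12)

  h <- makeHset(c(1, 2, 3), c(0.15, 0.25, 0.35), rep(0.1, 3))
  eg2 <- mrEgger(h)
  expect_equal(eg2@intercept, 0.05, tolerance = 1e-10)
  expect_equal(effectSize(eg2@slope), 0.1, tolerance = 1e-10)

  set.seed(5)
  bx <- runif(8, 0.1, 1); by <- 0.2 * bx + rnorm(8, 0.03, 0.02)
  sey <- runif(8, 0.05, 0.2)
  hr <- makeHset(bx, by, sey)
  egr <- mrEgger(hr)
  ref <- lm(by ~ bx, weights = 1 / sey^2)
  expect_equal(effectSize(egr@slope), unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(egr@intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  sig <- summary(ref)$sigma
  expect_equal(stdError(egr@slope),
               unname(coef(summary(ref))[2, 2]) / min(sig, 1),
               tolerance = 1e-10)

  # orientation invariance: flipping row signs on input changes nothing
  flip <- c(1, -1, 1, -1, 1, -1, 1, -1)
  hFlip <- makeHset(bx * flip, by * flip, sey)
  egf <- mrEgger(hFlip)
  expect_equal(effectSize(egf@slope), effectSize(egr@slope))
  expect_equal(egf@intercept, egr@intercept)

  expect_error(mrEgger(makeHset(c(1, 1, 1), c(0.1, 0.2, 0.3), rep(0.1, 3))),
               "collinearity")
  expect_error(mrEgger(makeHset(c(1, 2), c(0.1, 0.2), rep(0.1, 2))),
               "at least 3")
})

test_that("weighted median interpolates the cumulative weight midpoints", {
  expect_equal(weightedMedianEstimate(c(0.1, 0.2, 0.3), rep(1, 3)), 0.2)
  expect_equal(weightedMedianEstimate(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.7)),
               0.26667, tolerance = 1e-4)
  # hand interpolation: s = (0.05, 0.20, 0.65); 0.2 + 0.1 * 0.3/0.45
  expect_equal(weightedMedianEstimate(c(0.3, 0.1, 0.2), c(0.7, 0.1, 0.2)),
               0.2 + 0.1 * 0.3 / 0.45)
  h <- makeHset(rep(1, 3), c(0.1, 0.2, 0.3), rep(0.1, 3))
  wm1 <- weightedMedian(h, nBoot = 50, seed = 7)
  wm2 <- weightedMedian(h, nBoot = 50, seed = 7)
  expect_equal(effectSize(wm1), 0.2)
  expect_identical(stdError(wm1), stdError(wm2))  # determinism contract
  expect_error(weightedMedian(makeHset(1, 0.1, 0.1)), "at least 3")
})

test_that("all estimators agree when every instrument has the same ratio", {
  bx <- c(0.2, 0.45, 0.8, 1.2, 1.6)
  h <- makeHset(bx, 0.25 * bx, rep(0.08, 5))
  expect_equal(effectSize(mrIVW(h)), 0.25, tolerance = 1e-12)
  expect_equal(effectSize(mrEgger(h)@slope), 0.25, tolerance = 1e-10)
  expect_equal(effectSize(weightedMedian(h, 10, seed = 1)), 0.25)
})

test_that("leave-one-out exposes influential instruments", {
  h2 <- makeHset(c(0.5, 0.4), c(0.1, 0.05), c(0.1, 0.1))
  loo2 <- leaveOneOut(h2)
  expect_equal(effectSize(loo2[["rs1"]]), effectSize(waldRatio(0.4, 0.05, 0.1)))
  expect_equal(effectSize(loo2[["rs2"]]), effectSize(waldRatio(0.5, 0.1, 0.1)))
  expect_equal(methodTag(loo2[["rs1"]]), "loo:rs1")

  withSeed(13, {
    bx <- runif(10, 0.2, 0.6)
    by <- 0.2 * bx + rnorm(10, 0, 0.02)
    h <- makeHset(bx, by, rep(0.05, 10))
    full <- mrIVW(h)
    loo <- leaveOneOut(h)
    for (e in loo)
      expect_lt(abs(effectSize(e) - effectSize(full)), 2 * stdError(full))
  })

  # a planted outlier moves the estimate most when removed
  bx <- rep(0.5, 8)
  by <- c(0.2 * bx[1:7], 1.5)
  h <- makeHset(bx, by, rep(0.05, 8))
  full <- effectSize(mrIVW(h))
  shifts <- vapply(leaveOneOut(h), function(e) abs(effectSize(e) - full),
                   numeric(1))
  expect_equal(names(which.max(shifts)), "rs8")
})

test_that("odds-ratio view matches the published formatting", {
  e0 <- makeHset(1, 0, 0.1)
  or0 <- toOddsRatio(mrIVW(e0))
  expect_equal(or0$OR, 1)
  expect_equal(or0$ciLow * or0$ciHigh, 1, tolerance = 1e-12)

  est <- new("EffectEstimate", beta = 0.09531, se = 0.03717,
             pvalue = 2 * pnorm(-0.09531 / 0.03717), method = "ivw_random",
             k = 4L, outcomeScale = "log-odds")
  or <- toOddsRatio(est)
  expect_equal(round(or$OR, 2), 1.10)
  expect_equal(round(or$ciLow, 2), 1.02)
  expect_equal(round(or$ciHigh, 2), 1.18)

  est2 <- new("EffectEstimate", beta = log(3.11), se = 0.1,
              pvalue = 2 * pnorm(-log(3.11) / 0.1), method = "wald", k = 1L,
              outcomeScale = "log-odds")
  expect_equal(toOddsRatio(est2)$OR, 3.11)
  sdEst <- new("EffectEstimate", beta = 0.1, se = 0.1,
               pvalue = 2 * pnorm(-1), method = "wald", k = 1L,
               outcomeScale = "sd")
  expect_error(toOddsRatio(sdEst), "SD scale")
})

test_that("fixed-effects meta-analysis pools by inverse variance", {
  mk <- function(b, se) new("EffectEstimate", beta = b, se = se,
                            pvalue = 2 * pnorm(-abs(b / se)),
                            method = "ivw_random", k = 4L,
                            outcomeScale = "log-odds")
  single <- metaFixed(list(mk(0.1, 0.05)))
  expect_equal(effectSize(single), 0.1)
  expect_equal(stdError(single), 0.05)

  sym <- metaFixed(list(mk(0.1, 0.05), mk(0.1, 0.05)))
  expect_equal(effectSize(sym), 0.1)
  expect_equal(stdError(sym), 0.035355, tolerance = 1e-4)

  two <- metaFixed(list(mk(0.1, 0.05), mk(0.2, 0.1)))
  expect_equal(effectSize(two), 0.12)
  expect_equal(stdError(two), 0.044721, tolerance = 1e-4)
  expect_lt(stdError(two), 0.05)

  # independent cross-check against metafor's fixed-effects model
  skip_if_not_installed("metafor")
  rma <- metafor::rma(yi = c(0.1, 0.2), sei = c(0.05, 0.1), method = "FE")
  expect_equal(effectSize(two), as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(stdError(two), rma$se, tolerance = 1e-10)

  mixed <- list(mk(0.1, 0.05),
                new("EffectEstimate", beta = 0.1, se = 0.05,
                    pvalue = 2 * pnorm(-2), method = "ivw_random", k = 2L,
                    outcomeScale = "sd"))
  expect_error(metaFixed(mixed), "mixed outcome scales")
})

test_that("IVW recovers the chain total effect across seeded replicates", {
  # no-pleiotropy generator, modest case/control and quantitative sample
  # sizes; mean estimate over replicates should sit within 2 Monte-Carlo
  # SEs of the analytic total effect
  reps <- 50
  est <- numeric(reps)
  truthTotal <- NA_real_
  for (s in seq_len(reps)) {
    cfg <- simConfig(seed = 6000 + s, mSnps = 600, blockSize = 6,
                     nInstruments = c(nafld = 20, fi = 20, fg = 10,
                                      shbg = 20, bt = 20),
                     n = c(nafld = 2e4, fi = 5e4, fg = 5e4, shbg = 5e4,
                           bt = 5e4, pcos = 5e4))
    truth <- simulateDagTruth(cfg)
    truthTotal <- truth@totalEffect
    ds <- simulateSummaryStudy(truth)
    h <- quickHset(ds, "nafld", "pcos")
    est[s] <- effectSize(mrIVW(h))
  }
  mcSE <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - truthTotal), 2 * mcSE)
})
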
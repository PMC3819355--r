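test_that("addNoise draws seeded Gaussian noise of the requested SD", {
  sig <- activationSignal(designSpec("block"), psc = 1)
  expect_identical(addNoise(sig, 0), samples(sig))      # sd -> 0 limit
  y1 <- addNoise(sig, 2, seed = 9)
  y2 <- addNoise(sig, 2, seed = 9)
  expect_identical(y1, y2)                              # seeded
  expect_false(identical(y1, addNoise(sig, 2, seed = 10)))
  # law of large numbers at n = 1e5
  long <- addNoise(numeric(1e5), 3, seed = 1)
  expect_equal(sd(long), 3, tolerance = 0.02)
  expect_equal(mean(long), 0, tolerance = 0.05)
})

test_that("ar1 noise has the requested marginal SD and autocorrelation", {
  e <- addNoise(numeric(2e4), 2, seed = 5, type = "ar1", rho = 0.3)
  expect_equal(sd(e), 2, tolerance = 0.05)
  expect_equal(cor(e[-1], e[-length(e)]), 0.3, tolerance = 0.05)
})

test_that("fitGlm matches the closed-form OLS solution", {
  # hand-computed 5-point example: x = 0..4, y below;
  # Sxx = 10, Sxy = 8 => slope 0.8, intercept 1.4
  x <- 0:4
  y <- c(1, 3, 2, 5, 4)
  fit <- fitGlm(y, x)
  expect_equal(unname(fit$coefficients), c(1.4, 0.8))
  X <- cbind(1, x)
  expect_equal(unname(fit$coefficients),
               unname(drop(solve(t(X) %*% X) %*% t(X) %*% y)))
  # and agrees with lm() on random data, including SEs and p-values
  set.seed(2)
  xr <- matrix(rnorm(60), 30, 2)
  yr <- 1 + xr %*% c(0.5, -2) + rnorm(30)
  fit2 <- fitGlm(yr, xr)
  ref <- summary(lm(yr ~ xr))$coefficients
  expect_equal(unname(fit2$coefficients), unname(ref[, 1]))
  expect_equal(unname(fit2$se), unname(ref[, 2]))
  expect_equal(unname(fit2$pvalue), unname(ref[, 4]))
})

test_that("a noiseless series is fit exactly", {
  sig <- activationSignal(designSpec("block"), psc = 1)
  fit <- fitGlm(samples(sig), samples(sig) - baseline(sig))
  expect_equal(unname(fit$coefficients), c(100, 1), tolerance = 1e-9)
  expect_lt(fit$sigma2, 1e-18)
  expect_error(fitGlm(samples(sig), cbind(1:100, 2 * (1:100))),
               "rank deficient")
})

test_that("p-values are uniform under the null", {
  x <- samples(activationSignal(designSpec("block"), psc = 1)) - 100
  set.seed(33)
  pv <- replicate(2000, fitGlm(rnorm(100), x)$pvalue[2])
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.001)
})

test_that("detection decisions follow the design's contrast", {
  sig <- activationSignal(designSpec("block"), psc = 5)
  y <- addNoise(sig, 0.1, seed = 1)
  fit <- fitGlm(y, samples(sig) - 100)
  expect_true(testDetection(fit, "block")$reject)     # t far beyond critical
  # two identical condition responses: rejection rate ~ alpha
  sigs <- activationSignal(designSpec("contrast"), psc = 1)
  x1 <- samples(sigs$cond1) - 100
  x2 <- (samples(sigs$cond2) - 100) * 2   # unit amplitude each
  set.seed(7)
  rej <- replicate(600, {
    y <- 100 + x1 + x2 + rnorm(100)       # equal unit effects
    testDetection(fitGlm(y, cbind(x1, x2)), "contrast")$reject
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("empirical power is seeded and matches the analytic oracle", {
  cfg <- simConfig(nReps = 500, rngSeed = 12)
  p1 <- empiricalPower(designSpec("block"), 1, 2, cfg)
  p2 <- empiricalPower(designSpec("block"), 1, 2, cfg)
  expect_identical(power(p1), power(p2))
  for (sn in c(1, 2, 5)) {
    emp <- power(empiricalPower(designSpec("block"), 1, sn, cfg))
    ora <- analyticPowerOracle(designSpec("block"), 1, sn)
    expect_lt(abs(emp - ora),
              3 * sqrt(ora * (1 - ora) / 500) + 1 / 500)
  }
  # contrast design: oracle built from the same GLM geometry
  empC <- power(empiricalPower(designSpec("contrast"), 1, 1,
                               simConfig(nReps = 1500, rngSeed = 12)))
  oraC <- analyticPowerOracle(designSpec("contrast"), 1, 1)
  expect_lt(abs(empC - oraC), 3 * sqrt(oraC * (1 - oraC) / 1500) + 1 / 1500)
})

test_that("AR(1) noise lowers event-related power slightly", {
  # temporal autocorrelation inflates the variance of the OLS estimate
  # (partly offset by the naive test's anti-conservatism); at rho 0.2 the
  # ER cell drops by ~0.03 and the block cell barely moves
  cfgA <- simConfig(nReps = 4000, rngSeed = 18)
  pBlock <- power(empiricalPower(designSpec("block"), 1, 2, cfgA,
                                 noiseType = "ar1", rho = 0.2))
  expect_lt(abs(pBlock - analyticPowerOracle(designSpec("block"), 1, 2)),
            0.05)
  erFixed <- designSpec("event_related", rngSeed = 5)
  pEr <- power(empiricalPower(erFixed, 1, 1, cfgA, redrawEvents = FALSE,
                              noiseType = "ar1", rho = 0.2))
  pErWhite <- analyticPowerOracle(erFixed, 1, 1)
  expect_lt(pEr, pErWhite - 0.01)
  expect_gt(pEr, pErWhite - 0.08)
})

test_that("oracle limits behave: huge noise gives alpha, alpha -> 1 gives 1", {
  expect_equal(analyticPowerOracle(designSpec("block"), 1, 1e6), 0.05,
               tolerance = 1e-4)
  expect_equal(analyticPowerOracle(designSpec("block"), 1, 1,
                                   alpha = 0.999), 1, tolerance = 2e-3)
})

test_that("reference tables are deterministic and scale with psc", {
  cfg <- simConfig(nReps = 150, noiseSdGrid = c(0.5, 1, 2, 5),
                   pscGrid = c(1, 2), rngSeed = 21)
  t1 <- referenceTable(designSpec("block"), cfg)
  t2 <- referenceTable(designSpec("block"), cfg)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 8)
  p1 <- t1[t1$psc == 1, ]
  p2 <- t1[t1$psc == 2, ]
  expect_equal(p2$def2, 2 * p1$def2)            # homogeneity in psc
  expect_equal(p2$def4, 2 * p1$def4)
  # every metric is non-increasing in sigma_N within fixed psc
  for (cl in paste0("def", c(1, 2, 4, 5)))
    expect_true(all(diff(p1[[cl]]) <= 1e-12))
  # power non-increasing up to Monte-Carlo error
  expect_true(all(diff(p1$power) <= 0.12))
})

test_that("event-related tables use one placement and redraw for power", {
  cfg <- simConfig(nReps = 50, noiseSdGrid = c(0.1, 0.2), pscGrid = c(1, 2),
                   rngSeed = 3)
  tab <- referenceTable(designSpec("event_related", rngSeed = 8), cfg)
  # sigma_S from a single placement: def4 scales exactly across the grid
  expect_equal(tab$def4[tab$psc == 2], 2 * tab$def4[tab$psc == 1])
  expect_equal(tab$def4[1] / tab$def4[2], 2, tolerance = 1e-9)
})

test_that("matched SD-based CNR implies matched power for block and ER", {
  # block and event-related designs share the GLM geometry, so equal
  # cnr_sd means equal noncentrality; check on a grid of matched pairs.
  blockSd <- signalSd(activationSignal(designSpec("block"), psc = 1))
  erSpec <- designSpec("event_related", rngSeed = 5)
  erSd <- signalSd(activationSignal(erSpec, psc = 1))
  for (sn in c(1, 2, 4)) {
    pBlock <- analyticPowerOracle(designSpec("block"), 1, sn)
    # noise level matched so that the ER cell has the same cnr_sd
    pEr <- analyticPowerOracle(erSpec, 1, sn * erSd / blockSd, nDesigns = 1,
                               seed = 5)
    expect_lt(abs(pBlock - pEr), 0.02)
  }
  # one empirical spot check at matched cnr_sd
  pE <- power(empiricalPower(erSpec, 1, 1 * erSd / blockSd,
                             simConfig(nReps = 800, rngSeed = 14),
                             redrawEvents = FALSE))
  expect_lt(abs(pE - analyticPowerOracle(designSpec("block"), 1, 1)), 0.15)
})
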
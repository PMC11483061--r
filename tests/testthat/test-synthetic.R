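test_that("generators are reproducible and carry ground truth", {
  a <- genBrownian(5, DTrue = 10, L = 50, dt = 0.01, nSteps = 20, seed = 3)
  b <- genBrownian(5, DTrue = 10, L = 50, dt = 0.01, nSteps = 20, seed = 3)
  expect_identical(coords(a), coords(b))
  expect_s4_class(groundTruth(a), "GroundTruth")
  expect_equal(groundTruth(a)@parameters$DTrue, 10)
  ## per-particle sub-streams: adding particles keeps existing paths
  c6 <- genBrownian(6, DTrue = 10, L = 50, dt = 0.01, nSteps = 20, seed = 3)
  expect_identical(coords(c6)[, 1:5, ], coords(a))
  r1 <- genRotational(0.05, dt = 0.02, nSteps = 30, seed = 4)
  r2 <- genRotational(0.05, dt = 0.02, nSteps = 30, seed = 4)
  expect_identical(coords(r1), coords(r2))
})

test_that("degenerate generator limits behave as closed forms demand", {
  still <- genBrownian(3, DTrue = 0, L = 50, dt = 0.1, nSteps = 10, seed = 1)
  expect_true(all(apply(coords(still), c(2, 3), function(x)
    max(x) - min(x)) == 0))
  frozen <- genRotational(0, dt = 0.1, nSteps = 10, seed = 1)
  expect_equal(coords(frozen)[11, , ], coords(frozen)[1, , ])
  acf <- rotACF(frozen, nVectors = 10, maxLag = 1)
  expect_equal(curveValues(acf), rep(1, length(lagTimes(acf))))
  expect_error(genBrownian(2, DTrue = 1e6, L = 10, dt = 1, nSteps = 2,
                           seed = 1), "L/4")
})

test_that("Brownian MSD matches 6 D t within Monte-Carlo error", {
  traj <- genBrownian(60, DTrue = 100, L = 500, dt = 0.02, nSteps = 1500,
                      seed = 12, wrapped = FALSE)
  msd <- computeMSD(traj, maxLag = 10)
  keep <- lagTimes(msd) >= 2 & lagTimes(msd) <= 10
  relErr <- curveValues(msd)[keep] / (6 * 100 * lagTimes(msd)[keep]) - 1
  expect_lt(max(abs(relErr)), 0.25)
  expect_equal(curveValues(msd)[1], 0)
})

test_that("OU pressure series have the analytic autocovariance and eta", {
  sl <- genOUPressure(C0 = 500, tauC = 1, volume = 8000, temperature = 298,
                      dt = 0.1, nSteps = 4000, nTraj = 8, seed = 6)
  tr <- groundTruth(sl[[1]])
  expect_equal(tr@parameters$etaTrue,
               1e-29 * 8000 / (kBoltzmann * 298) * 500 * 1, tolerance = 1e-12)
  ## doubling tauC doubles the analytic viscosity
  sl2 <- genOUPressure(C0 = 500, tauC = 2, volume = 8000, temperature = 298,
                       dt = 0.1, nSteps = 100, nTraj = 2, seed = 6)
  expect_equal(groundTruth(sl2[[1]])@parameters$etaTrue,
               2 * tr@parameters$etaTrue)
  ## empirical ACF close to C0 exp(-t/tauC)
  acf <- pressureACF(sl, maxLag = 4)
  th <- 500 * exp(-lagTimes(acf) / 1)
  expect_lt(max(abs(curveValues(acf) - th)) / 500, 0.05)
  ## C0 = 0 collapses to a flat zero series
  expect_error(genOUPressure(C0 = -1, tauC = 1, volume = 1, temperature = 1,
                             dt = 0.1, nSteps = 10, nTraj = 2, seed = 1),
               "positive")
  z <- genOUPressure(C0 = 0, tauC = 1, volume = 8000, temperature = 298,
                     dt = 0.1, nSteps = 50, nTraj = 2, seed = 1)
  expect_equal(groundTruth(z[[1]])@parameters$etaTrue, 0)
  expect_equal(max(abs(tensorSamples(z[[1]]) -
                       rep(colMeans(tensorSamples(z[[1]])),
                           each = 50))), 0)
})

test_that("telegraph timelines honor absorbing limits and the exact ACF", {
  on <- genTelegraphContacts(4, data.frame(weight = 1, kOff = 0), kOn = 1,
                             dt = 0.05, nSteps = 40, seed = 2)
  expect_true(all(on@states))  # kOff = 0: contacts are absorbing
  off <- genTelegraphContacts(4, data.frame(weight = 1, kOff = 1), kOn = 0,
                              dt = 0.05, nSteps = 40, seed = 2)
  expect_false(any(off@states))
  expect_error(genTelegraphContacts(4, data.frame(weight = 1, kOff = 30),
                                    kOn = 1, dt = 0.05, nSteps = 10, seed = 1),
               "too coarse")
  ## single-component empirical ACF vs the two-state closed form
  rc <- data.frame(weight = 1, kOff = 0.5)
  tl <- genTelegraphContacts(400, rc, kOn = 0.05, dt = 0.05, nSteps = 8000,
                             seed = 8)
  acf <- contactACF(tl, maxLag = 10, nLags = 40)
  th <- telegraphContactACF(lagTimes(acf), rc, kOn = 0.05, dt = 0.05)
  expect_lt(max(abs(curveValues(acf) - th)), 0.05)
})

test_that("concentration series obey the generalized Stokes-Einstein identity", {
  ser <- genConcentrationSeries("mooney", list(S = 2.8, K = 0.53), D0 = 10,
                                sigma = 0, phiGrid = seq(0, 0.3, 0.05),
                                noiseSD = 0, seed = 1)
  expect_equal(ser$Dt * ser$etaR / 10, rep(1, nrow(ser)))
  expect_equal(ser$etaR[1], 1)              # phi = 0 row
  expect_equal(ser$Dt[1], 10)
  expect_equal(ser$Dr[1], 10)
  expect_equal(ser$c, 1430 * ser$phi)
  expect_error(genConcentrationSeries("mooney", list(S = 2.5, K = 4), D0 = 1,
                                      sigma = 0, phiGrid = c(0, 0.3),
                                      noiseSD = 0, seed = 1), "pole")
  expect_error(genConcentrationSeries("quadratic", list(b = 10), D0 = 1,
                                      sigma = 0, phiGrid = c(0, 0.5),
                                      noiseSD = 0, seed = 1), "0.35")
})
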
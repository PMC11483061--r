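test_that("MSD handles deterministic paths exactly", {
  nf <- 21
  coords <- array(0, dim = c(nf, 2, 3))
  coords[, 1, 1] <- 3 * (0:(nf - 1))       # ballistic, v = 3 A/ns
  traj <- Trajectory(times = 0:(nf - 1), coords = coords, box = 1e4,
                     particles = particleTable(1:2), wrapped = FALSE)
  msd <- computeMSD(traj, selection = 1L, maxLag = 10)
  expect_equal(curveValues(msd), 9 * lagTimes(msd)^2)
  still <- computeMSD(traj, selection = 2L, maxLag = 10)
  expect_equal(curveValues(still), rep(0, length(lagTimes(still))))
  expect_error(computeMSD(wrapTrajectory(traj), maxLag = 5), "unwrap")
})

test_that("diffusion fit takes the slope and ignores the intercept", {
  lag <- seq(0.5, 12, by = 0.5)
  mk <- function(m) new("MSDCurve", lag = lag, msd = m, selection = "x",
                        counts = rep(10, length(lag)))
  expect_equal(fitDiffusion(mk(6 * 50 * lag)), 50)
  expect_equal(fitDiffusion(mk(6 * 50 * lag + 30)), 50)   # anomalous offset
  expect_error(fitDiffusion(mk(6 * lag), window = c(20, 30)), "window")
})

test_that("Brownian fixtures recover DTrue within three standard errors", {
  traj <- genBrownian(nParticles = 120, DTrue = 100, L = 600, dt = 0.02,
                      nSteps = 2500, seed = 21)
  u <- unwrapTrajectory(traj)
  perGroup <- vapply(split(seq_len(120), rep(1:6, each = 20)), function(g) {
    fitDiffusion(computeMSD(u, selection = g, maxLag = 10))
  }, numeric(1))
  se <- sd(perGroup) / sqrt(length(perGroup))
  expect_lt(abs(mean(perGroup) - 100), 3 * se + 1e-9)
})

test_that("xi factor matches its closed form and root", {
  expect_equal(xiFactor(0, 50), 2.837297)
  expect_equal(xiFactor(20, 80), 2.837297 - 4 * pi * 400 / (3 * 6400))
  expect_equal(xiFactor(20, 80), 2.575498, tolerance = 1e-6)
  r0 <- 80 * sqrt(3 * 2.837297 / (4 * pi))
  expect_equal(xiFactor(r0, 80), 0, tolerance = 1e-12)
})

test_that("periodic-box corrections reproduce reference arithmetic", {
  ## independent SI evaluation: kB T xi/(6 pi eta L) in m^2/s -> A^2/ns
  kT <- 1.380649e-23 * 298
  corr <- kT * 2.837297 / (6 * pi * 0.347e-3 * 100e-10) * 1e11
  expect_equal(pbcCorrectTranslational(10, eta = 0.347, L = 100),
               10 + corr, tolerance = 1e-10)
  expect_equal(pbcCorrectTranslational(10, eta = 0.347, L = 100), 27.85,
               tolerance = 1e-3)
  ## xi = 0 leaves the raw value untouched
  r0 <- 100 * sqrt(3 * 2.837297 / (4 * pi))
  expect_equal(pbcCorrectTranslational(10, 0.347, 100, Rp = r0), 10)
  ## rotational reference value
  corrR <- kT / (6 * 0.334e-3 * (50e-10)^3) * 1e-9
  expect_equal(pbcCorrectRotational(0, eta = 0.334, L = 50), corrR,
               tolerance = 1e-10)
  expect_equal(pbcCorrectRotational(0, eta = 0.334, L = 50), 0.0164,
               tolerance = 1e-2)
  ## corrections vanish as the box grows (1/L and 1/L^3 scaling)
  cT <- function(L) pbcCorrectTranslational(0, 0.347, L)
  expect_equal(cT(1e6) / cT(100), 1e-4, tolerance = 1e-3)
  cR <- function(L) pbcCorrectRotational(0, 0.347, L)
  expect_equal(cR(1e6) / cR(100), 1e-12, tolerance = 1e-6)
  expect_lt(cR(1e6) / 0.05, 1e-6)
  ## correction decreases with viscosity
  expect_gt(pbcCorrectRotational(0, 0.2, 50), pbcCorrectRotational(0, 0.4, 50))
})

test_that("viscosity rescaling is exact, trivial on equality, invertible", {
  expect_equal(rescaleByViscosityRatio(622.5), 622.5 * 0.334 / 0.890)
  expect_equal(rescaleByViscosityRatio(622.5), 233.6, tolerance = 1e-4)
  expect_equal(rescaleByViscosityRatio(7, 0.5, 0.5), 7)
  expect_equal(rescaleByViscosityRatio(0), 0)
  back <- rescaleByViscosityRatio(rescaleByViscosityRatio(12.3), 0.890, 0.334)
  expect_equal(back, 12.3)
  te <- transportEstimate(10, "translational", eta = 0.347, L = 100)
  expect_equal(te@rescaled, te@pbcCorrected * 0.334 / 0.890)
})

test_that("rotational ACF and fit recover the isotropic decay", {
  traj <- genRotational(DrTrue = 0.05, dt = 0.05, nSteps = 4000, seed = 7)
  acf <- rotACF(traj, nVectors = 150, maxLag = 15)
  th <- exp(-6 * 0.05 * lagTimes(acf))
  expect_lt(max(abs(curveValues(acf) - th)), 0.15)
  fit <- fitRotational(acf, window = c(0, 15))
  expect_lt(abs(fit@Dr / 0.05 - 1), 0.25)
  expect_equal(fit@Dr, 1 / (6 * fit@tau))
  ## more vectors only reduce variance, not the expectation
  acf1 <- rotACF(traj, nVectors = 25, maxLag = 5, seed = 2)
  expect_lt(max(abs(curveValues(acf1) - exp(-0.3 * lagTimes(acf1)))), 0.25)
  expect_error(rotACF(genBrownian(2, 1, 100, 0.1, 5, 1)), "C-alpha")
})

test_that("rotational relaxation combines fit components as harmonic weights", {
  lag <- seq(0, 20, by = 0.25)
  exact <- exactExpCurve(lag, c(0.4, 0.6), c(1, 10))
  fit <- fitRotational(exact)
  expect_equal(fit@tau, 1 / (0.4 / 1 + 0.6 / 10), tolerance = 1e-4)
  expect_equal(fit@tau, 2.1739, tolerance = 1e-4)
  single <- exactExpCurve(lag, 1, 5)
  fs <- fitRotational(single)
  expect_equal(fs@tau, 5, tolerance = 1e-4)
  expect_equal(fs@Dr, 1 / 30, tolerance = 1e-4)
})

test_that("tensor relaxation time matches a second arithmetic route", {
  expect_equal(tauFromTensor(0.05, 0.05, 0.05), 1 / (6 * 0.05))
  for (D in c(0.01, 0.2, 3)) expect_equal(tauFromTensor(D, D, D), 1 / (6 * D))
  ## independent evaluation written out term by term
  D1 <- 0.02; D2 <- 0.05; D3 <- 0.08
  Dm <- mean(c(D1, D2, D3))
  ref <- (1 / (Dm + D1) + 1 / (Dm + D2) + 1 / (Dm + D3) +
            sum(c(D1, D2, D3)) / (D1 * D2 + D2 * D3 + D3 * D1)) / 15
  expect_equal(tauFromTensor(D1, D2, D3), ref)
  tf <- rotationalFitFromTensor(D1, D2, D3)
  expect_equal(tf@Dr, 1 / (6 * ref))
  expect_error(tauFromTensor(0, 0.1, 0.1), "positive")
})

test_that("Stokes-Einstein radii invert the forward relations", {
  Dt <- stokesEinsteinDt(20, eta = 1)
  Dr <- stokesEinsteinDr(20, eta = 1)
  hr <- hydrodynamicRadii(Dt, Dr, eta = 1)
  expect_equal(hr@translational, 20, tolerance = 1e-12)
  expect_equal(hr@rotational, 20, tolerance = 1e-12)
  ## a sphere obeying both laws has equal radii by construction
  expect_equal(hr@translational, hr@rotational)
})

test_that("Brownian and rotational fixtures built from one sphere agree", {
  eta <- 0.9; Rh <- 18
  DtTrue <- stokesEinsteinDt(Rh, eta)
  DrTrue <- stokesEinsteinDr(Rh, eta)
  traj <- genBrownian(80, DtTrue, L = 500, dt = 0.05, nSteps = 1200,
                      seed = 31, wrapped = FALSE)
  Dt <- fitDiffusion(computeMSD(traj, maxLag = 10))
  rot <- genRotational(DrTrue, dt = 0.1, nSteps = 3000, seed = 32)
  Dr <- fitRotational(rotACF(rot, nVectors = 150, maxLag = 15),
                      window = c(0, 15))@Dr
  hr <- hydrodynamicRadii(Dt, Dr, eta)
  expect_lt(abs(hr@translational / Rh - 1), 0.15)
  expect_lt(abs(hr@rotational / Rh - 1), 0.15)
})

test_that("the Stokes-Einstein deviation isolates the cluster factor", {
  r <- stokesEinsteinRatio(Dc = 5, D0 = 10, etaC = 2, eta0 = 1)
  expect_equal(unname(r["deviation"]), 1)
  expect_equal(unname(stokesEinsteinRatio(3, 3, 7, 7)), c(1, 1, 1),
               ignore_attr = TRUE)
  ## sigma > 0 series deviates by (1 + sigma phi)^(-1/3) for translation
  ser <- genConcentrationSeries("quadratic", list(b = 20), D0 = 10,
                                sigma = 15, phiGrid = c(0, 0.1, 0.2, 0.3),
                                noiseSD = 0, seed = 1)
  dev <- vapply(2:4, function(i) {
    unname(stokesEinsteinRatio(ser$Dt[i], ser$Dt[1], ser$etaR[i],
                               1)["deviation"])
  }, numeric(1))
  expect_equal(dev, (1 + 15 * ser$phi[2:4])^(-1 / 3), tolerance = 1e-10)
})
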
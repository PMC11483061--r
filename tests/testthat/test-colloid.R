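test_that("RDF resolves fixed separations and the ideal gas", {
  ## two molecules at fixed distance: a single occupied bin
  traj <- twoParticleTraj(rep(12.3, 4), L = 60)
  rdf <- computeRDF(traj, binWidth = 1, rmax = 25)
  expect_equal(which(rdf@g > 0), 13L)  # bin [12, 13)
  ## uniform random placements: g(r) = 1 within sampling error on each bin
  set.seed(19)
  L <- 50; nm <- 30; nf <- 80
  co <- array(runif(nf * nm * 3, 0, L), dim = c(nf, nm, 3))
  gas <- Trajectory(times = 0:(nf - 1), coords = co, box = L, wrapped = TRUE)
  rdf2 <- computeRDF(gas, binWidth = 1, rmax = 24)
  nPairs <- nm * (nm - 1) / 2
  expected <- 4 * pi * rdf2@r^2 * 1 / L^3 * nf * nPairs
  tol <- 5 / sqrt(expected)   # ~5 sigma Poisson band per bin
  expect_true(all(abs(rdf2@g - 1) < pmax(tol, 0.2)))
  expect_error(computeRDF(traj, binWidth = 1, rmax = 40), "L/2")
  expect_error(computeRDF(traj, groupA = 1L), "pair")
})

test_that("B2 integrals match analytic step and square-well forms", {
  r <- seq(0.25, 30, by = 0.5)
  step <- new("RDFCurve", r = r, g = as.numeric(r > 10), pairSelection = "x",
              nFrames = 1, rmax = 30)
  expect_equal(b2FromRDF(step), 2 * pi * 10^3 / 3, tolerance = 2e-3)
  flat <- new("RDFCurve", r = r, g = rep(1, length(r)), pairSelection = "x",
              nFrames = 1, rmax = 30)
  ## zero up to the (tiny) unsampled-core contribution below the first bin
  expect_lt(abs(b2FromRDF(flat)), 2 * pi * r[1]^3 / 3 + 1e-9)
  ## square well: g = 0 below sigma, g0 on [sigma, lambda sigma], 1 beyond
  sigma <- 8; lambda <- 1.5; g0 <- 3
  gsw <- ifelse(r < sigma, 0, ifelse(r < lambda * sigma, g0, 1))
  sw <- new("RDFCurve", r = r, g = gsw, pairSelection = "x", nFrames = 1,
            rmax = 30)
  analytic <- 2 * pi * sigma^3 / 3 -
    (g0 - 1) * 2 * pi * ((lambda * sigma)^3 - sigma^3) / 3
  expect_equal(b2FromRDF(sw), analytic, tolerance = 5e-3)
  expect_error(b2FromRDF(sw, rmax = 50), "beyond")
})

test_that("hard-sphere volumes reproduce printed interaction-table values", {
  expect_equal(hardSphereVolume(15.40), 15303, tolerance = 2e-3)
  expect_equal(hardSphereVolume(12.07, 11.70), 7027, tolerance = 2e-3)
  ## heterotypic form reduces to homotypic at equal radii
  expect_equal(hardSphereVolume(9, 9), hardSphereVolume(9), tolerance = 1e-12)
  expect_error(hardSphereVolume(-1), "positive")
})

test_that("Baxter stickiness inverts the adhesive-sphere B2 relation", {
  expect_equal(baxterTau(-18403, 7027), 0.151, tolerance = 1e-3)
  expect_equal(baxterTau(102037, 27920), 2.895, tolerance = 1e-3)
  expect_equal(baxterTau(0, 1234), 0.25)
  expect_error(baxterTau(4 * 500, 500), "stickiness")
  ## round trip through the defining relation
  tauB <- baxterTau(-5000, 3000)
  expect_equal(4 * 3000 - 3000 / tauB, -5000)
})

test_that("KD conversion lands on the printed dissociation constants", {
  expect_equal(kdFromTau(1, 1.66054e6), 1)
  expect_equal(kdFromTau(baxterTau(-18403, 7027), hardSphereVolume(12.07)),
               34.1, tolerance = 2e-3)
  expect_equal(kdFromTau(baxterTau(-203652, 15303), 15303), 6.3,
               tolerance = 6e-3)
  expect_equal(kdFromTau(baxterTau(-653129, 33943), hardSphereVolume(12.05)),
               9.74, tolerance = 2e-3)
})

test_that("interaction records rebuild the printed table end-to-end", {
  ## pair, a1, a2, printed VHS, printed B2, printed tauB, printed KD,
  ## reference radius for KD (probe radius for heterotypic pairs, NA = VHS)
  rows <- list(
    list("SH3-GB1", 12.07, 11.70, 7027, -18403, 0.151, 34.1, 12.07),
    list("SH3-lysozyme", 12.05, 15.40, 10837, -199715, 0.045, 10.1, 12.05),
    list("SH3-BSA", 12.05, 25.58, 27920, 102037, 2.895, 655.3, 12.05),
    list("SH3-ovalbumin", 12.05, 28.11, 33943, -653129, 0.043, 9.74, 12.05),
    list("GB1-GB1", 11.70, NA, 6700, -17024, 0.153, 37.9, NA),
    list("lysozyme-lysozyme", 15.40, NA, 15303, -203652, 0.058, 6.3, NA))
  for (row in rows) {
    ## volumes from the radii agree with the printed volume to 0.2%
    expect_equal(hardSphereVolume(row[[2]], row[[3]]), row[[4]],
                 tolerance = 2e-3, label = row[[1]])
    ## tauB and KD from the printed volume agree to the printed precision
    rec <- colloidRecord(row[[1]], a1 = row[[2]], a2 = row[[3]],
                         B2 = row[[5]], referenceRadius = row[[8]],
                         VHS = row[[4]])
    expect_lt(abs(rec@tauB - row[[6]]),
              max(0.005 * row[[6]], 0.00051))
    expect_lt(abs(rec@kd - row[[7]]), max(0.005 * row[[7]], 0.051))
  }
  tab <- colloidTable(lapply(rows, function(row)
    colloidRecord(row[[1]], row[[2]], row[[3]], B2 = row[[5]],
                  referenceRadius = row[[8]], VHS = row[[4]])))
  expect_equal(nrow(tab), 6L)
  expect_named(tab, c("pair", "a1", "a2", "VHS", "B2", "rmax", "tauB", "KD"))
})

test_that("viscosity coefficient b bridges to tauB and back", {
  expect_equal(tauFromViscosityB(63.4), 0.033, tolerance = 1e-2)
  expect_equal(tauFromViscosityB(7.830), 1.0)
  expect_equal(tauFromViscosityB(viscosityBFromTau(0.05)), 0.05)
  expect_error(tauFromViscosityB(5.9), "non-positive")
})

test_that("concentration converts through the 1430 g/L coefficient", {
  expect_equal(concToPhi(1430), 1)
  expect_equal(concToPhi(0), 0)
  expect_equal(concToPhi(300), 0.2098, tolerance = 1e-3)
  expect_equal(phiToConc(concToPhi(123)), 123)
  ## the exploratory refit recovers a known slope
  phi <- seq(0.01, 0.3, by = 0.01)
  expect_equal(fitConcentrationCoefficient(1430 * phi, phi), 1430)
})

test_that("viscosity models fit exactly on noiseless data", {
  phi <- seq(0, 0.3, by = 0.025)
  quad <- genConcentrationSeries("quadratic", list(b = 63.4), D0 = 1,
                                 sigma = 0, phiGrid = phi, noiseSD = 0,
                                 seed = 1)
  fq <- fitViscosityModel(quad$phi, quad$etaR, "quadratic")
  expect_equal(unname(fittedParameters(fq)["b"]), 63.4, tolerance = 1e-9)
  ## all model curves pass through etaR = 1 at phi = 0
  for (m in c("einstein", "quadratic", "mooney"))
    expect_equal(evalViscosityModel(m, 0, list(b = 5, S = 3, K = 0.5)), 1)
  ## hard-sphere Mooney (S = 2.5, K = 0) recovered exactly
  hs <- genConcentrationSeries("mooney", list(S = 2.5, K = 0), D0 = 1,
                               sigma = 0, phiGrid = phi, noiseSD = 0, seed = 1)
  fm <- fitViscosityModel(hs$phi, hs$etaR, "mooney")
  expect_equal(unname(fittedParameters(fm)["S"]), 2.5, tolerance = 1e-6)
  expect_equal(unname(fittedParameters(fm)["K"]), 0, tolerance = 1e-6)
  ein <- fitViscosityModel(phi, 1 + 2.5 * phi, "einstein")
  expect_equal(ein@residual, 0)
  expect_length(fittedParameters(ein), 0)
})

test_that("quadratic and Mooney reduce toward Einstein at small phi", {
  phi <- 1e-3
  e <- evalViscosityModel("einstein", phi)
  q <- evalViscosityModel("quadratic", phi, list(b = 0))
  m <- evalViscosityModel("mooney", phi, list(S = 2.5, K = 0))
  expect_equal(q, e, tolerance = 1e-12)
  expect_lt(abs(m - e), 10 * phi^2)
})

test_that("cluster-diffusion fits recover sigma and reduce cleanly", {
  phi <- seq(0, 0.3, by = 0.025)
  etaModel <- list(model = "quadratic", parameters = c(b = 30))
  ## sigma = 0 data yields sigma = 0 and D = D0/etaR
  etaR <- evalViscosityModel("quadratic", phi, etaModel$parameters)
  f0 <- fitClusterDiffusion(phi, 10 / etaR, "translational", etaModel)
  expect_equal(unname(fittedParameters(f0)["sigma"]), 0, tolerance = 1e-8)
  expect_equal(unname(fittedParameters(f0)["D0"]), 10, tolerance = 1e-6)
  ## translational and rotational fits agree on shared sigma-generated data
  ser <- genConcentrationSeries("quadratic", list(b = 30), D0 = 10,
                                sigma = 20, phiGrid = phi, noiseSD = 0,
                                seed = 2)
  ft <- fitClusterDiffusion(ser$phi, ser$Dt, "translational", etaModel)
  fr <- fitClusterDiffusion(ser$phi, ser$Dr, "rotational", etaModel)
  expect_equal(unname(fittedParameters(ft)["sigma"]), 20, tolerance = 1e-6)
  expect_equal(unname(fittedParameters(fr)["sigma"]), 20, tolerance = 1e-6)
  expect_equal(attr(ft, "clusterSize"), 1 + 20 * phi)
})

test_that("characteristic diffusion length follows sqrt(D tau)", {
  expect_equal(characteristicDiffusionLength(9, 60), sqrt(540))
  expect_equal(round(characteristicDiffusionLength(9, 60)), 23)
  expect_equal(characteristicDiffusionLength(100, 1), 10)
  expect_equal(characteristicDiffusionLength(5, 0), 0)
})
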
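test_that("contact cutoff is strict and respects the minimum image", {
  tl49 <- contactTimeline(twoParticleTraj(4.9), cutoff = 5)
  expect_true(tl49@states[1, 1])
  tl51 <- contactTimeline(twoParticleTraj(5.1), cutoff = 5)
  expect_false(tl51@states[1, 1])
  tl50 <- contactTimeline(twoParticleTraj(5.0), cutoff = 5)
  expect_false(tl50@states[1, 1])   # strict <
  ## separation 0.9 L across the boundary is 0.1 L via the nearest image
  tlpb <- contactTimeline(twoParticleTraj(18, L = 20), cutoff = 5)
  expect_true(tlpb@states[1, 1])
  expect_error(contactTimeline(twoParticleTraj(1), selection = 1L),
               "at least 2")
})

test_that("an approach/retreat path flips state exactly at the crossing", {
  seps <- c(8, 6.5, 5.2, 4.6, 3.5, 4.8, 5.4, 7)
  tl <- contactTimeline(twoParticleTraj(seps), cutoff = 5)
  expect_equal(as.vector(tl@states), seps < 5)
})

test_that("contact detection agrees exactly with a brute-force oracle", {
  set.seed(42)
  L <- 30
  nAtoms <- 36
  molecule <- rep(1:6, each = 6)
  for (rep in 1:3) {
    xyz <- matrix(runif(nAtoms * 3, 0, L), ncol = 3)
    coords <- array(xyz, dim = c(1, nAtoms, 3))
    traj <- Trajectory(times = 0, coords = coords, box = L,
                       particles = particleTable(molecule), wrapped = TRUE)
    tl <- contactTimeline(traj, cutoff = 6)
    ref <- bruteContacts(xyz, molecule, rep(TRUE, nAtoms), L, cutoff = 6)
    ## align on pair keys: the timeline and oracle enumerate pairs in
    ## different orders
    key <- function(a, b) paste(a, b)
    ord <- match(key(tl@pairs[, 1], tl@pairs[, 2]), key(ref[, 1], ref[, 2]))
    expect_identical(as.logical(tl@states[1, ]), as.logical(ref[ord, 3]))
  }
})

test_that("residue contact density counts crowder atoms near C-alphas", {
  ## probe: 3 residues with C-alpha at x = 0, 10, 20; crowder atom at 6 A
  ## from residue 1 only
  coords <- array(0, dim = c(2, 4, 3))
  coords[, 2, 1] <- 10; coords[, 3, 1] <- 20
  coords[, 4, 1] <- -6
  traj <- Trajectory(times = 0:1, coords = coords, box = 200,
                     particles = particleTable(c(1, 1, 1, 2),
                                               residue = c(1, 2, 3, 1),
                                               isCalpha = c(TRUE, TRUE, TRUE,
                                                            FALSE)),
                     wrapped = TRUE)
  d <- residueContactDensity(traj, probe = 1, cutoff = 7)
  expect_equal(d$count, c(1, 0, 0))
  far <- traj
  far@coords[, 4, 1] <- -50
  expect_equal(residueContactDensity(far, probe = 1)$count, c(0, 0, 0))
  ## replicas give standard errors
  both <- residueContactDensity(list(traj, far), probe = 1)
  expect_equal(both$count, c(0.5, 0, 0))
  expect_equal(both$se, c(0.5 / sqrt(2) * sqrt(2), 0, 0))
  ## randomized placements agree with a brute-force double loop
  set.seed(7)
  n <- 20
  xyz <- matrix(runif(n * 3, 0, 25), ncol = 3)
  molecule <- c(rep(1L, 5), rep(2L, 15))
  tr <- Trajectory(times = 0, coords = array(xyz, dim = c(1, n, 3)), box = 25,
                   particles = particleTable(molecule,
                                             isCalpha = molecule == 1L),
                   wrapped = TRUE)
  d2 <- residueContactDensity(tr, probe = 1, cutoff = 7)
  ref <- vapply(1:5, function(i) {
    sum(vapply(6:20, function(j) {
      dx <- xyz[i, ] - xyz[j, ]
      dx <- dx - 25 * round(dx / 25)
      sum(dx^2) < 49
    }, logical(1)))
  }, numeric(1))
  expect_equal(d2$count, ref)
})

test_that("cluster decomposition separates direct and in-cluster partners", {
  ## chain A-B, B-C: probe A touches 1, clusters with 2
  pairs <- rbind(c(1, 2), c(2, 3), c(1, 3))
  mk <- function(states) ContactTimeline(pairs, times = 0,
                                         states = matrix(states, 1))
  chain <- clusterDecomposition(mk(c(TRUE, TRUE, FALSE)), 1, probe = 1)
  expect_equal(chain$direct, 1L)
  expect_equal(chain$inCluster, 2L)
  none <- clusterDecomposition(mk(rep(FALSE, 3)), 1, probe = 1)
  expect_equal(none$direct, 0L)
  expect_equal(none$inCluster, 0L)
  expect_equal(length(none$components), 3L)
  ## complete graph on 6 molecules: probe sees all 5 both ways
  p6 <- t(combn(1:6, 2))
  full <- ContactTimeline(p6, times = 0,
                          states = matrix(TRUE, 1, nrow(p6)))
  d <- clusterDecomposition(full, 1, probe = 1)
  expect_equal(d$direct, 5L)
  expect_equal(d$inCluster, 5L)
})

test_that("direct <= in-cluster <= N-1 holds on random timelines", {
  set.seed(11)
  pairs <- t(combn(1:7, 2))
  for (rep in 1:5) {
    states <- matrix(runif(10 * nrow(pairs)) < 0.25, 10)
    tl <- ContactTimeline(pairs, times = 0:9, states = states)
    rp <- clusterReport(tl, probe = 3)
    expect_true(all(rp@direct <= rp@inCluster))
    expect_true(all(rp@inCluster <= 6))
  }
})

test_that("contact ACF normalization and degenerate cases", {
  pairs <- rbind(c(1, 2), c(1, 3))
  ones <- ContactTimeline(pairs, times = 0:19,
                          states = matrix(TRUE, 20, 2))
  acf <- contactACF(ones, maxLag = 10)
  expect_equal(curveValues(acf), rep(1, length(lagTimes(acf))))
  single <- matrix(FALSE, 20, 2); single[5, 1] <- TRUE
  acf1 <- contactACF(ContactTimeline(pairs, times = 0:19, states = single),
                     maxLag = 10)
  expect_equal(curveValues(acf1)[-1], rep(0, length(lagTimes(acf1)) - 1L))
  expect_error(contactACF(ContactTimeline(pairs, times = 0:19,
                                          states = matrix(FALSE, 20, 2)),
                          maxLag = 5), "P\\(0\\)")
})

test_that("contact ACF is non-increasing for telegraph mixtures", {
  tl <- genTelegraphContacts(300, data.frame(weight = c(0.6, 0.4),
                                             kOff = c(2, 0.1),
                                             kOn = c(0.1, 0.005)),
                             dt = 0.02, nSteps = 20000, seed = 13)
  acf <- contactACF(tl, maxLag = 40, nLags = 60)
  expect_gt(min(diff(curveValues(acf))), -0.05)
})

test_that("survival fit recovers an exact triple exponential to 1%", {
  lag <- exp(seq(log(0.01), log(300), length.out = 80))
  curve <- exactExpCurve(lag, c(0.5, 0.3, 0.2), c(0.1, 3, 60))
  fit <- fitSurvival(curve)
  expect_false(fit@degenerate)
  expect_equal(fit@tau, c(0.1, 3, 60), tolerance = 0.01)
  expect_equal(fit@weights, c(0.5, 0.3, 0.2), tolerance = 0.01)
  expect_equal(sum(fit@weights), 1, tolerance = 1e-9)
})

test_that("a single-exponential input is flagged as degenerate", {
  lag <- exp(seq(log(0.05), log(100), length.out = 50))
  fit <- fitSurvival(exactExpCurve(lag, 1, 4))
  expect_true(fit@degenerate)
  ## the overall decay is still captured by the duplicated constants
  pred <- sum(fit@weights * exp(-10 / fit@tau))
  expect_equal(pred, exp(-10 / 4), tolerance = 0.01)
})

test_that("Z-score diagnostics distinguish drift from equilibrium", {
  times <- seq(0, 2000, by = 2)
  flat <- convergenceZscore(times, rep(3.2, length(times)), window = 400)
  expect_equal(flat@z, rep(0, length(flat@z)))
  ## white noise stays below 1 nearly everywhere across seeds
  frac <- vapply(1:4, function(s) {
    set.seed(s)
    z <- convergenceZscore(times, rnorm(length(times)), window = 400)
    mean(z@z > 1)
  }, numeric(1))
  expect_lt(mean(frac), 0.35)
  ## a step change halfway produces a clear peak above 1
  stepped <- c(rep(0, 500), rep(2, 501)) + rnorm(1001, sd = 0.2)
  zs <- convergenceZscore(times, stepped, window = 400)
  expect_gt(max(zs@z), 1)
  expect_gt(zs@times[which.max(zs@z)], 300)
  expect_error(convergenceZscore(times, rep(1, length(times)), window = 4000),
               "shorter")
})
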
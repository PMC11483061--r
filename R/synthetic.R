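## Seeded synthetic generators with recorded ground truth.  These stand in
## for MD trajectories when validating the estimators: each generator's
## sampling distribution has a closed form (free Brownian MSD, isotropic
## rotational P2 decay, Ornstein-Uhlenbeck autocovariance, two-state Markov
## contact ACF, Mooney/quadratic concentration laws), so parameter recovery
## can be asserted against known truth.

## Derive a reproducible sub-stream seed (< 2^31) from a master seed.
.substream <- function(seed, i) {
  ((seed %% 1000003) * 1009 + (i %% 1000003) * 9973) %% 2147483647
}

#' Generate free Brownian trajectories in a periodic cubic box
#'
#' Independent Gaussian displacement steps per particle and dimension with
#' variance `2 * DTrue * dt`, so the mean-square displacement is exactly
#' `6 DTrue t` in expectation.  Both the wrapped coordinates (returned) and
#' the continuous ground-truth path (in the metadata) are retained.  Random
#' streams are drawn per particle from sub-seeds of `seed`, so enlarging
#' `nParticles` leaves earlier particles' paths unchanged.
#'
#' @param nParticles number of independent particles (each its own molecule).
#' @param DTrue diffusion coefficient, square Angstrom per ns.
#' @param L cubic box edge, Angstrom.
#' @param dt time step, ns.  Must satisfy `sqrt(2 DTrue dt) < L/4` so that
#'   wrapped paths can be unwrapped unambiguously.
#' @param nSteps number of steps (the trajectory has `nSteps + 1` frames).
#' @param seed master seed.
#' @param wrapped return wrapped (`TRUE`, default) or continuous coordinates.
#' @return A [Trajectory-class]; `groundTruth(x)` records `DTrue` and the
#'   metadata element `unwrapped` holds the continuous path.
#' @export
genBrownian <- function(nParticles, DTrue, L, dt, nSteps, seed,
                        wrapped = TRUE) {
  if (DTrue < 0) stop("'DTrue' must be non-negative")
  stepSD <- sqrt(2 * DTrue * dt)
  if (stepSD >= L / 4)
    stop("step size sqrt(2 D dt) must be below L/4; reduce 'dt'")
  nf <- nSteps + 1L
  un <- array(0, dim = c(nf, nParticles, 3L))
  for (p in seq_len(nParticles)) {
    set.seed(.substream(seed, p))
    start <- stats::runif(3L, 0, L)
    steps <- matrix(stats::rnorm(nSteps * 3L, sd = stepSD), ncol = 3L)
    un[, p, ] <- rbind(start, sweep(apply(steps, 2L, cumsum), 2L, start, "+"))
  }
  truth <- GroundTruth("brownian",
                       list(DTrue = DTrue, L = L, dt = dt, nSteps = nSteps),
                       seed)
  traj <- Trajectory(times = (seq_len(nf) - 1L) * dt,
                     coords = if (wrapped) un %% L else un, box = L,
                     particles = particleTable(seq_len(nParticles)),
                     wrapped = wrapped,
                     metadata = list(groundTruth = truth, unwrapped = un))
  traj
}

## Rodrigues rotation matrix for a rotation vector (axis * angle).
.rotationMatrix <- function(omega) {
  theta <- sqrt(sum(omega^2))
  if (theta < 1e-300) return(diag(3))
  n <- omega / theta
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Generate a rigid body undergoing isotropic rotational diffusion
#'
#' A fixed template of `nSites` points (labeled as C-alpha sites of one
#' molecule) is rotated by composing small random rotations whose rotation
#' vectors have independent Gaussian components with variance `2 DrTrue dt`.
#' This construction is isotropic, and in the small-step limit the
#' second-Legendre orientation autocorrelation decays as `exp(-6 DrTrue t)`.
#'
#' @param DrTrue rotational diffusion coefficient, 1/ns.
#' @param dt time step, ns; the per-step rotation `sqrt(6 DrTrue dt)` must be
#'   well below 1 radian.
#' @param nSteps number of steps.
#' @param nSites number of template sites (at least 4; non-collinear by
#'   construction).
#' @param seed master seed.
#' @param siteRadius template radius, Angstrom.
#' @return An unwrapped [Trajectory-class] of the rotating body;
#'   `groundTruth(x)` records `DrTrue`.
#' @export
genRotational <- function(DrTrue, dt, nSteps, nSites = 5, seed,
                          siteRadius = 10) {
  if (DrTrue < 0) stop("'DrTrue' must be non-negative")
  if (nSites < 4) stop("'nSites' must be at least 4")
  if (sqrt(6 * DrTrue * dt) > 0.5)
    stop("per-step rotation too large for small-rotation composition; ",
         "reduce 'dt'")
  set.seed(.substream(seed, 1L))
  ## random but well-conditioned template: points on a sphere, centered
  template <- matrix(stats::rnorm(nSites * 3L), ncol = 3L)
  template <- siteRadius * template / sqrt(rowSums(template^2))
  template <- sweep(template, 2L, colMeans(template))
  nf <- nSteps + 1L
  coords <- array(0, dim = c(nf, nSites, 3L))
  coords[1L, , ] <- template
  set.seed(.substream(seed, 2L))
  omegas <- matrix(stats::rnorm(nSteps * 3L, sd = sqrt(2 * DrTrue * dt)),
                   ncol = 3L)
  R <- diag(3)
  for (s in seq_len(nSteps)) {
    R <- .rotationMatrix(omegas[s, ]) %*% R
    coords[s + 1L, , ] <- template %*% t(R)
  }
  truth <- GroundTruth("rotational",
                       list(DrTrue = DrTrue, dt = dt, nSteps = nSteps,
                            nSites = nSites), seed)
  Trajectory(times = (seq_len(nf) - 1L) * dt, coords = coords,
             box = 100 * siteRadius,
             particles = particleTable(rep(1L, nSites), isCalpha = TRUE),
             wrapped = FALSE,
             metadata = list(groundTruth = truth))
}

#' Generate Ornstein-Uhlenbeck pressure-tensor series
#'
#' Each of the nine tensor components of each trajectory is an independent
#' stationary Gaussian AR(1) process with autocovariance
#' `C0 * exp(-t / tauC)` (exact discretization).  The analytic Green-Kubo
#' viscosity of such a series is `eta = V / (kB T) * C0 * tauC` (with unit
#' conversions), recorded in the ground truth, which makes these ensembles
#' an oracle for the whole viscosity pipeline.
#'
#' @param C0 autocovariance at zero lag, bar^2.
#' @param tauC correlation time, ps.
#' @param volume system volume, cubic Angstrom.
#' @param temperature temperature, K.
#' @param dt sampling interval, ps (must be below `tauC`).
#' @param nSteps samples per trajectory.
#' @param nTraj number of independent trajectories (at least 2).
#' @param seed master seed; trajectory `i` uses sub-stream `i`.
#' @param diagonalMean mean added to the three diagonal components, bar
#'   (default 1; exercises the per-component mean removal downstream).
#' @return List of `nTraj` [PressureSeries-class] objects, each carrying the
#'   shared [GroundTruth-class] (element `etaTrue` in cP).
#' @export
genOUPressure <- function(C0, tauC, volume, temperature, dt, nSteps, nTraj,
                          seed, diagonalMean = 1) {
  if (C0 < 0 || tauC <= 0) stop("'C0' and 'tauC' must be positive")
  if (tauC <= dt) stop("'tauC' must exceed the sampling interval 'dt'")
  if (nTraj < 2) stop("at least two trajectories are required")
  rho <- exp(-dt / tauC)
  innovSD <- sqrt(C0 * (1 - rho^2))
  etaTrue <- .GK_PREFACTOR(volume, temperature) * C0 * tauC
  truth <- GroundTruth("ou_pressure",
                       list(C0 = C0, tauC = tauC, volume = volume,
                            temperature = temperature, dt = dt,
                            etaTrue = etaTrue), seed)
  times <- (seq_len(nSteps) - 1L) * dt * 1e-3  # ps -> ns
  means <- rep(c(diagonalMean, 0), c(1L, 2L))[c(1, 2, 2, 2, 1, 2, 2, 2, 1)]
  lapply(seq_len(nTraj), function(i) {
    set.seed(.substream(seed, i))
    tens <- matrix(0, nSteps, 9L)
    for (k in 1:9) {
      x <- numeric(nSteps)
      x[1] <- stats::rnorm(1L, sd = sqrt(C0))
      innov <- stats::rnorm(nSteps - 1L, sd = innovSD)
      x <- stats::filter(c(x[1], innov), rho, method = "recursive")
      tens[, k] <- as.numeric(x) + means[k]
    }
    PressureSeries(times, tens, volume, temperature,
                   metadata = list(groundTruth = truth, trajectory = i))
  })
}

#' Generate telegraph (two-state Markov) contact timelines
#'
#' Each molecule pair is an independent two-state chain simulated in
#' discrete time with per-step flip probabilities `kOn * dt` (off to on) and
#' `kOff * dt` (on to off); initial states are drawn from the stationary
#' distribution.  Pairs are assigned deterministically to the supplied rate
#' components in proportion to their weights.  The exact expected contact
#' autocorrelation of the ensemble is returned by [telegraphContactACF()].
#'
#' Because initial states are stationary, the normalized ACF mixes the
#' components with amplitudes proportional to `weight * pOn`: with a single
#' shared on-rate, slow components dominate.  Supplying a per-component
#' `kOn` column (e.g. proportional to `kOff`, giving every component the
#' same stationary on-probability) keeps all amplitudes comparable, which
#' is the regime in which a multi-exponential survival fit can recover
#' every time constant.
#'
#' @param nPairs number of pairs.
#' @param rateComponents `data.frame` (or matrix) with columns `weight` and
#'   `kOff` (1/ns), and optionally `kOn`; weights must be positive and sum
#'   to 1.
#' @param kOn shared on-rate, 1/ns (ignored when `rateComponents` has a
#'   `kOn` column).
#' @param dt frame spacing, ns; `dt * max(rate)` must not exceed 0.1.
#' @param nSteps number of steps (`nSteps + 1` frames).
#' @param seed master seed.
#' @return A [ContactTimeline-class]; the ground truth records the rate
#'   mixture and per-pair component assignment.
#' @export
genTelegraphContacts <- function(nPairs, rateComponents, kOn = NULL, dt,
                                 nSteps, seed) {
  rc <- as.data.frame(rateComponents)
  if (!all(c("weight", "kOff") %in% names(rc)))
    stop("'rateComponents' needs columns 'weight' and 'kOff'")
  if (is.null(rc$kOn)) {
    if (is.null(kOn)) stop("supply 'kOn' or a kOn column in rateComponents")
    rc$kOn <- kOn
  }
  if (any(rc$weight <= 0) || abs(sum(rc$weight) - 1) > 1e-8)
    stop("component weights must be positive and sum to 1")
  if (any(rc$kOff < 0) || any(rc$kOn < 0)) stop("rates must be non-negative")
  if (dt * max(c(rc$kOff, rc$kOn)) > 0.1)
    stop("dt * max(rate) exceeds 0.1: discretization too coarse")
  ## deterministic proportional assignment of pairs to components
  bounds <- round(cumsum(rc$weight) * nPairs)
  component <- rep(seq_len(nrow(rc)), times = diff(c(0L, bounds)))
  length(component) <- nPairs
  component[is.na(component)] <- nrow(rc)

  nf <- nSteps + 1L
  states <- matrix(FALSE, nf, nPairs)
  pOnStep <- rc$kOn[component] * dt
  pOffStep <- rc$kOff[component] * dt
  kSum <- rc$kOn[component] + rc$kOff[component]
  pStat <- ifelse(kSum > 0, rc$kOn[component] / kSum, 1)
  set.seed(.substream(seed, 1L))
  states[1L, ] <- stats::runif(nPairs) < pStat
  for (s in 2:nf) {
    u <- stats::runif(nPairs)
    prev <- states[s - 1L, ]
    states[s, ] <- ifelse(prev, u >= pOffStep, u < pOnStep)
  }
  truth <- GroundTruth("telegraph",
                       list(kOn = rc$kOn, kOff = rc$kOff, weight = rc$weight,
                            dt = dt, component = component), seed)
  ContactTimeline(pairs = cbind(seq_len(nPairs), seq_len(nPairs) + nPairs),
                  times = (seq_len(nf) - 1L) * dt, states = states,
                  metadata = list(groundTruth = truth))
}

#' Closed-form contact autocorrelation of a telegraph mixture
#'
#' Exact normalized intermittent contact autocorrelation of the two-state
#' Markov mixture produced by [genTelegraphContacts()].  Per component with
#' stationary on-probability `p = kOn/(kOn + kOff)` and relaxation rate
#' `lambda = kOn + kOff`, the unnormalized correlation is
#' `p * (p + (1 - p) exp(-lambda t))`; components are mixed by weight and
#' normalized by the zero-lag value.  With `discrete = TRUE` (the default,
#' matching the first-order discrete-time simulation) the relaxation rate is
#' replaced by `-log(1 - lambda dt)/dt`.
#'
#' @param lag lag times, ns.
#' @param rateComponents as in [genTelegraphContacts()].
#' @param kOn on-rate, 1/ns.
#' @param dt frame spacing (required when `discrete = TRUE`).
#' @param discrete use the discrete-chain relaxation rate.
#' @return Numeric vector of P(lag), with P(0) = 1.
#' @export
telegraphContactACF <- function(lag, rateComponents, kOn = NULL, dt = NULL,
                                discrete = !is.null(dt)) {
  rc <- as.data.frame(rateComponents)
  if (is.null(rc$kOn)) rc$kOn <- kOn
  lambda <- rc$kOn + rc$kOff
  if (discrete) {
    if (is.null(dt)) stop("'dt' is required for the discrete-chain form")
    lambda <- -log(1 - lambda * dt) / dt
  }
  p <- ifelse(rc$kOn + rc$kOff > 0, rc$kOn / (rc$kOn + rc$kOff), 1)
  u0 <- sum(rc$weight * p)
  vapply(lag, function(t) {
    sum(rc$weight * p * (p + (1 - p) * exp(-lambda * t))) / u0
  }, numeric(1))
}

#' Generate a concentration series from a viscosity/cluster model
#'
#' Builds a table of relative viscosity and diffusion coefficients on a
#' volume-fraction grid from a chosen viscosity model (quadratic
#' `1 + 2.5 phi + b phi^2` or Mooney `exp(S phi / (1 - K phi))`) combined
#' with the effective-cluster diffusion laws
#' `Dt = D0 / (etaR (1 + sigma phi)^(1/3))` and
#' `Dr = D0 / (etaR (1 + sigma phi))`, plus multiplicative Gaussian noise.
#'
#' @param model `"quadratic"` or `"mooney"`.
#' @param parameters named list/vector: `b` for quadratic, `S` and `K` for
#'   Mooney.
#' @param D0 dilute-limit diffusion coefficient (units carried through).
#' @param sigma effective cluster-size coefficient (>= 0); the cluster size
#'   at volume fraction phi is `1 + sigma * phi`.
#' @param phiGrid volume fractions, within `[0, 0.35]`.
#' @param noiseSD relative standard deviation of the multiplicative noise.
#' @param seed master seed.
#' @param concentrationCoefficient g/L per unit volume fraction for the
#'   concentration column.
#' @return `data.frame(phi, c, etaR, Dt, Dr)` with attribute `groundTruth`.
#' @export
genConcentrationSeries <- function(model = c("quadratic", "mooney"),
                                   parameters, D0, sigma, phiGrid,
                                   noiseSD = 0, seed = 1,
                                   concentrationCoefficient = 1430) {
  model <- match.arg(model)
  if (any(phiGrid < 0 | phiGrid > 0.35))
    stop("'phiGrid' must lie within [0, 0.35]")
  if (noiseSD < 0) stop("'noiseSD' must be non-negative")
  if (sigma < 0) stop("'sigma' must be non-negative")
  etaR <- evalViscosityModel(model, phiGrid, parameters)
  cluster <- 1 + sigma * phiGrid
  Dt <- D0 / (etaR * cluster^(1 / 3))
  Dr <- D0 / (etaR * cluster)
  set.seed(.substream(seed, 1L))
  jitter <- function(x) x * (1 + stats::rnorm(length(x), sd = noiseSD))
  out <- data.frame(phi = phiGrid, c = concentrationCoefficient * phiGrid,
                    etaR = jitter(etaR), Dt = jitter(Dt), Dr = jitter(Dr))
  attr(out, "groundTruth") <- GroundTruth(
    "concentration_series",
    c(list(model = model, D0 = D0, sigma = sigma, noiseSD = noiseSD),
      as.list(parameters)), seed)
  out
}
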
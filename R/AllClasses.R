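#' @import methods
NULL

## Relative tolerance used when checking that a time grid is uniform.
.SPACING_RTOL <- 1e-6

.isUniform <- function(times, rtol = .SPACING_RTOL) {
  if (length(times) < 3L) return(TRUE)
  dt <- diff(times)
  (max(dt) - min(dt)) <= rtol * max(abs(dt))
}

## ---------------------------------------------------------------------------
## Trajectory
## ---------------------------------------------------------------------------

#' Trajectory: labeled particle coordinates in a periodic cubic box
#'
#' Holds frames of particle coordinates together with per-frame cubic box
#' edge lengths and a particle label table.  All analysis formulas in the
#' package assume a cubic box, so non-cubic systems are rejected at load
#' time.  Coordinates are in Angstrom, times in ns.
#'
#' @slot times numeric, frame times in ns; strictly increasing and uniformly
#'   spaced within a small relative tolerance.
#' @slot coords numeric array `[nFrames, nParticles, 3]`, Angstrom.
#' @slot box numeric, cubic box edge length L per frame, Angstrom.
#' @slot particles `data.frame` with columns `molecule` (integer id),
#'   `residue` (integer index within molecule), `isHeavy`, `isCalpha`,
#'   `isSolvent` (logical).  C-alpha particles are a subset of heavy
#'   particles.
#' @slot wrapped logical; `TRUE` if coordinates are wrapped into the primary
#'   box image.
#' @slot metadata list; free-form provenance, including the [GroundTruth] of
#'   synthetic trajectories.
#'
#' @seealso [Trajectory()], [unwrapTrajectory()], [computeMSD()]
#' @export
setClass("Trajectory",
  representation(
    times = "numeric",
    coords = "array",
    box = "numeric",
    particles = "data.frame",
    wrapped = "logical",
    metadata = "list"
  )
)

setValidity("Trajectory", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "'coords' must be an [nFrames, nParticles, 3] array")
  if (length(object@times) != d[1])
    msg <- c(msg, "length(times) must equal the number of coordinate frames")
  if (length(object@box) != d[1])
    msg <- c(msg, "one box edge length is required per frame")
  if (any(object@box <= 0)) msg <- c(msg, "box edge lengths must be positive")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "frame times must be strictly increasing")
  if (!.isUniform(object@times))
    msg <- c(msg, "frame times must be uniformly spaced")
  p <- object@particles
  need <- c("molecule", "residue", "isHeavy", "isCalpha", "isSolvent")
  if (!all(need %in% names(p))) {
    msg <- c(msg, sprintf("'particles' must have columns: %s",
                          paste(need, collapse = ", ")))
  } else {
    if (nrow(p) != d[2])
      msg <- c(msg, "one particle label row is required per particle")
    if (any(p$isCalpha & !p$isHeavy))
      msg <- c(msg, "C-alpha particles must be a subset of heavy particles")
  }
  if (length(object@wrapped) != 1L)
    msg <- c(msg, "'wrapped' must be a single logical")
  ## Unwrapped coordinates must be continuous: no per-frame jump >= L/2.
  if (length(msg) == 0L && isFALSE(object@wrapped) && d[1] > 1L) {
    steps <- object@coords[-1L, , , drop = FALSE] -
      object@coords[-d[1], , , drop = FALSE]
    lim <- object@box[-d[1]] / 2
    if (any(abs(steps) >= lim))
      msg <- c(msg, "unwrapped trajectory has a frame-to-frame jump >= L/2")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Trajectory
#'
#' @param times frame times in ns.
#' @param coords `[nFrames, nParticles, 3]` array of coordinates (Angstrom).
#' @param box cubic box edge length(s), Angstrom; recycled to one per frame.
#' @param particles particle label `data.frame` (see [Trajectory-class]); by
#'   default every particle is its own single-atom heavy molecule.
#' @param wrapped are the coordinates wrapped into the primary image?
#' @param metadata free-form provenance list.
#' @return A [Trajectory-class] object.
#' @export
Trajectory <- function(times, coords, box, particles = NULL, wrapped = TRUE,
                       metadata = list()) {
  if (is.matrix(coords)) dim(coords) <- c(1L, dim(coords))
  nf <- dim(coords)[1]
  np <- dim(coords)[2]
  if (is.null(particles)) particles <- particleTable(rep(seq_len(np), each = 1L))
  new("Trajectory", times = as.numeric(times), coords = coords,
      box = rep_len(as.numeric(box), nf), particles = particles,
      wrapped = wrapped, metadata = metadata)
}

#' Build a particle label table
#'
#' @param molecule integer molecule id per particle.
#' @param residue integer residue index per particle (default: running index
#'   within each molecule).
#' @param isHeavy,isCalpha,isSolvent logical classification per particle.
#'   C-alpha implies heavy.
#' @return `data.frame` suitable for the `particles` slot of a [Trajectory-class].
#' @export
particleTable <- function(molecule, residue = NULL, isHeavy = TRUE,
                          isCalpha = FALSE, isSolvent = FALSE) {
  molecule <- as.integer(molecule)
  n <- length(molecule)
  if (is.null(residue))
    residue <- stats::ave(rep(1L, n), molecule, FUN = seq_along)
  data.frame(molecule = molecule, residue = as.integer(residue),
             isHeavy = rep_len(isHeavy, n), isCalpha = rep_len(isCalpha, n),
             isSolvent = rep_len(isSolvent, n))
}

## ---------------------------------------------------------------------------
## PressureSeries
## ---------------------------------------------------------------------------

#' PressureSeries: time-stamped pressure-tensor samples
#'
#' A uniformly spaced time series of the nine components of the
#' instantaneous pressure tensor, with the (fixed) system volume and
#' temperature needed for the Green-Kubo viscosity integral.
#'
#' @slot times numeric, sample times in ns, uniformly spaced.
#' @slot tensors numeric matrix `[nSamples, 9]`, components in bar, column
#'   order xx, xy, xz, yx, yy, yz, zx, zy, zz.
#' @slot volume system volume in cubic Angstrom.
#' @slot temperature temperature in K.
#' @slot metadata list, free-form provenance.
#' @seealso [PressureSeries()], [pressureACF()], [runningViscosity()]
#' @export
setClass("PressureSeries",
  representation(times = "numeric", tensors = "matrix", volume = "numeric",
                 temperature = "numeric", metadata = "list")
)

setValidity("PressureSeries", function(object) {
  msg <- character()
  if (ncol(object@tensors) != 9L)
    msg <- c(msg, "'tensors' must have 9 columns (3x3 tensor components)")
  if (nrow(object@tensors) != length(object@times))
    msg <- c(msg, "one tensor sample is required per time stamp")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "sample times must be strictly increasing")
  if (!.isUniform(object@times))
    msg <- c(msg, "sample spacing must be constant")
  if (length(object@volume) != 1L || object@volume <= 0)
    msg <- c(msg, "'volume' must be a single positive number")
  if (length(object@temperature) != 1L || object@temperature <= 0)
    msg <- c(msg, "'temperature' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a PressureSeries
#'
#' @param times sample times in ns.
#' @param tensors `[nSamples, 9]` matrix of pressure-tensor components (bar).
#' @param volume system volume, cubic Angstrom.
#' @param temperature temperature, K.
#' @param metadata provenance list.
#' @return A [PressureSeries-class] object.
#' @export
PressureSeries <- function(times, tensors, volume, temperature,
                           metadata = list()) {
  new("PressureSeries", times = as.numeric(times), tensors = as.matrix(tensors),
      volume = volume, temperature = temperature, metadata = metadata)
}

## ---------------------------------------------------------------------------
## Curves and fits
## ---------------------------------------------------------------------------

#' CorrelationCurve: a lag-resolved correlation function
#'
#' @slot lag numeric, lag times (ns unless noted by the producing function).
#' @slot value numeric, mean correlation value per lag.
#' @slot spread numeric, per-lag spread (standard deviation across replicas);
#'   may be `NA` when only one replica is available.
#' @slot counts numeric, number of averaged terms per lag.
#' @slot metadata list.
#' @export
setClass("CorrelationCurve",
  representation(lag = "numeric", value = "numeric", spread = "numeric",
                 counts = "numeric", metadata = "list")
)

setValidity("CorrelationCurve", function(object) {
  n <- length(object@lag)
  if (length(object@value) != n)
    return("'value' must have one entry per lag")
  if (length(object@spread) != n || length(object@counts) != n)
    return("'spread' and 'counts' must have one entry per lag")
  TRUE
})

CorrelationCurve <- function(lag, value, spread = rep(NA_real_, length(lag)),
                             counts = rep(1, length(lag)), metadata = list()) {
  new("CorrelationCurve", lag = lag, value = value, spread = spread,
      counts = counts, metadata = metadata)
}

#' MSDCurve: mean-square displacement versus lag time
#'
#' @slot lag numeric, lag times in ns (first entry 0).
#' @slot msd numeric, mean-square displacement in square Angstrom.
#' @slot selection character, molecule selection label.
#' @slot counts numeric, number of (molecule, time-origin) pairs per lag.
#' @export
setClass("MSDCurve",
  representation(lag = "numeric", msd = "numeric", selection = "character",
                 counts = "numeric")
)

setValidity("MSDCurve", function(object) {
  msg <- character()
  if (length(object@msd) != length(object@lag))
    msg <- c(msg, "'msd' must have one entry per lag")
  if (any(object@msd < 0)) msg <- c(msg, "MSD values must be non-negative")
  if (length(object@lag) && object@lag[1] == 0 && object@msd[1] != 0)
    msg <- c(msg, "MSD at zero lag must be zero")
  if (length(msg)) msg else TRUE
})

#' ViscosityCurve: running Green-Kubo integrals across trajectories
#'
#' @slot tau numeric, lag grid in ps.
#' @slot etaRuns numeric matrix `[nLag, nTrajectories]`, per-trajectory
#'   running viscosity integral, cP.
#' @slot etaMean,etaSD numeric, ensemble mean and standard deviation per lag.
#' @slot volume,temperature system volume (cubic Angstrom) and temperature (K).
#' @export
setClass("ViscosityCurve",
  representation(tau = "numeric", etaRuns = "matrix", etaMean = "numeric",
                 etaSD = "numeric", volume = "numeric", temperature = "numeric")
)

setValidity("ViscosityCurve", function(object) {
  msg <- character()
  if (nrow(object@etaRuns) != length(object@tau))
    msg <- c(msg, "'etaRuns' must have one row per lag")
  if (length(object@etaMean) != length(object@tau) ||
      length(object@etaSD) != length(object@tau))
    msg <- c(msg, "'etaMean' and 'etaSD' must have one entry per lag")
  if (length(object@tau) && object@tau[1] == 0 &&
      any(abs(object@etaRuns[1, ]) > 1e-12))
    msg <- c(msg, "running integrals must start at zero")
  if (any(object@etaSD < 0, na.rm = TRUE))
    msg <- c(msg, "ensemble standard deviations must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ViscosityEstimate: extrapolated Green-Kubo viscosity
#'
#' @slot eta extrapolated viscosity (tau to infinity plateau), cP.
#' @slot tauMax largest lag used in the weighted fit, ps.
#' @slot sigmaPowerLaw named numeric `(A, b)` of the uncertainty power law
#'   `sigma(tau) = A * tau^b`.
#' @slot fitParameters named numeric `(A, alpha, tau1, tau2)` of the
#'   time-integrated double-exponential model (see [extrapolateEta()]).
#' @slot uncertainty cross-trajectory uncertainty of the estimate, cP.
#' @slot metadata list (records the functional form used).
#' @export
setClass("ViscosityEstimate",
  representation(eta = "numeric", tauMax = "numeric",
                 sigmaPowerLaw = "numeric", fitParameters = "numeric",
                 uncertainty = "numeric", metadata = "list")
)

#' TransportEstimate: a diffusion coefficient with its corrected variants
#'
#' @slot kind `"translational"` (values in square Angstrom per ns) or
#'   `"rotational"` (values in 1/ns).
#' @slot raw value measured under periodic boundary conditions.
#' @slot pbcCorrected finite-size corrected value.
#' @slot rescaled water-model viscosity rescaled value.
#' @slot se standard error across replicas (NA when unknown).
#' @slot inputs list of correction inputs (eta cP, L Angstrom, Rp Angstrom,
#'   T K, rescaling viscosity pair).
#' @export
setClass("TransportEstimate",
  representation(kind = "character", raw = "numeric", pbcCorrected = "numeric",
                 rescaled = "numeric", se = "numeric", inputs = "list")
)

setValidity("TransportEstimate", function(object) {
  if (!object@kind %in% c("translational", "rotational"))
    return("'kind' must be 'translational' or 'rotational'")
  TRUE
})

#' RotationalFit: double-exponential fit of an orientation ACF
#'
#' @slot w amplitude weight of the first exponential, in `[0, 1]`.
#' @slot tau1,tau2 time constants, ns.
#' @slot tau overall relaxation time `(w/tau1 + (1-w)/tau2)^-1`, ns.
#' @slot Dr rotational diffusion coefficient `1/(6 tau)`, 1/ns.
#' @slot method `"acf"` (fit to the P2 autocorrelation) or `"tensor"`
#'   (closed-form relaxation time from an anisotropic diffusion tensor).
#' @export
setClass("RotationalFit",
  representation(w = "numeric", tau1 = "numeric", tau2 = "numeric",
                 tau = "numeric", Dr = "numeric", method = "character")
)

setValidity("RotationalFit", function(object) {
  msg <- character()
  if (object@w < 0 || object@w > 1) msg <- c(msg, "'w' must lie in [0, 1]")
  if (object@tau1 <= 0 || object@tau2 <= 0)
    msg <- c(msg, "time constants must be positive")
  if (abs(object@Dr - 1 / (6 * object@tau)) > 1e-8 * object@Dr)
    msg <- c(msg, "Dr must equal 1/(6 tau)")
  if (length(msg)) msg else TRUE
})

#' HydrodynamicRadius: Stokes-Einstein radii from both diffusion modes
#'
#' @slot translational radius from `Dt = kB T / (6 pi eta Rh)`, Angstrom.
#' @slot rotational radius from `Dr = kB T / (8 pi eta Rh^3)`, Angstrom.
#' @slot inputs list recording `Dt`, `Dr`, `eta`, `temperature`.
#' @export
setClass("HydrodynamicRadius",
  representation(translational = "numeric", rotational = "numeric",
                 inputs = "list")
)

setValidity("HydrodynamicRadius", function(object) {
  if (any(c(object@translational, object@rotational) <= 0, na.rm = TRUE))
    return("radii must be positive")
  TRUE
})

#' SurvivalFit: triple-exponential contact-survival fit
#'
#' @slot weights numeric length 3 on the probability simplex (sums to 1).
#' @slot tau numeric length 3, strictly ordered time constants, ns.
#' @slot residual weighted residual sum of squares of the best fit.
#' @slot degenerate `TRUE` when two time constants collapsed, i.e. the data
#'   supported fewer than three exponentials.
#' @export
setClass("SurvivalFit",
  representation(weights = "numeric", tau = "numeric", residual = "numeric",
                 degenerate = "logical")
)

setValidity("SurvivalFit", function(object) {
  msg <- character()
  if (length(object@weights) != 3L || length(object@tau) != 3L)
    msg <- c(msg, "'weights' and 'tau' must each have length 3")
  else {
    if (any(object@weights < -1e-9) || abs(sum(object@weights) - 1) > 1e-6)
      msg <- c(msg, "weights must be non-negative and sum to 1")
    if (!object@degenerate && any(diff(object@tau) <= 0))
      msg <- c(msg, "time constants must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Contacts
## ---------------------------------------------------------------------------

#' ContactTimeline: boolean contact state per molecule pair per frame
#'
#' @slot pairs integer matrix `[nPairs, 2]` of molecule id pairs (first id
#'   less than second: the contact relation is symmetric).
#' @slot times numeric, frame times in ns (uniform spacing).
#' @slot states logical matrix `[nFrames, nPairs]`.
#' @slot metadata list (cutoff used, generator ground truth, ...).
#' @export
setClass("ContactTimeline",
  representation(pairs = "matrix", times = "numeric", states = "matrix",
                 metadata = "list")
)

setValidity("ContactTimeline", function(object) {
  msg <- character()
  if (ncol(object@pairs) != 2L) msg <- c(msg, "'pairs' must have two columns")
  else if (any(object@pairs[, 1] >= object@pairs[, 2]))
    msg <- c(msg, "pairs must be stored with first id < second id")
  if (nrow(object@states) != length(object@times))
    msg <- c(msg, "'states' must have one row per frame")
  if (ncol(object@states) != nrow(object@pairs))
    msg <- c(msg, "'states' must have one column per pair")
  if (!.isUniform(object@times))
    msg <- c(msg, "frame times must be uniformly spaced")
  if (length(msg)) msg else TRUE
})

ContactTimeline <- function(pairs, times, states, metadata = list()) {
  pairs <- as.matrix(pairs)
  swap <- pairs[, 1] > pairs[, 2]
  if (any(swap)) pairs[swap, ] <- pairs[swap, 2:1]
  new("ContactTimeline", pairs = pairs, times = as.numeric(times),
      states = states, metadata = metadata)
}

#' ClusterReport: contact-graph decomposition around a probe molecule
#'
#' @slot probe molecule id of the probe.
#' @slot times frame times, ns.
#' @slot direct number of molecules in direct contact with the probe per frame.
#' @slot inCluster number of molecules sharing the probe's connected
#'   component per frame (excluding the probe itself).
#' @slot components list of per-frame connected components (each a list of
#'   integer vectors of molecule ids).
#' @export
setClass("ClusterReport",
  representation(probe = "integer", times = "numeric", direct = "numeric",
                 inCluster = "numeric", components = "list")
)

setValidity("ClusterReport", function(object) {
  if (any(object@direct > object@inCluster))
    return("direct partner counts cannot exceed in-cluster partner counts")
  TRUE
})

#' ConvergenceSeries: windowed Z-score equilibration diagnostic
#'
#' @slot times start times of the evaluation windows, ns.
#' @slot z non-negative Z-scores comparing short- and long-time averages.
#' @slot window short-average window length, ns.
#' @slot shortMean,longMean the windowed and remaining-trajectory averages.
#' @export
setClass("ConvergenceSeries",
  representation(times = "numeric", z = "numeric", window = "numeric",
                 shortMean = "numeric", longMean = "numeric")
)

setValidity("ConvergenceSeries", function(object) {
  if (any(object@z < 0, na.rm = TRUE)) return("Z-scores must be non-negative")
  TRUE
})

## ---------------------------------------------------------------------------
## Colloid theory
## ---------------------------------------------------------------------------

#' RDFCurve: center-of-mass radial distribution function
#'
#' @slot r numeric, radial bin centers, Angstrom (uniform bins).
#' @slot g numeric, g(r) values (non-negative).
#' @slot pairSelection character label of the molecule pair selection.
#' @slot nFrames number of frames averaged.
#' @slot rmax upper radius of the histogram, Angstrom.
#' @export
setClass("RDFCurve",
  representation(r = "numeric", g = "numeric", pairSelection = "character",
                 nFrames = "numeric", rmax = "numeric")
)

setValidity("RDFCurve", function(object) {
  msg <- character()
  if (length(object@g) != length(object@r))
    msg <- c(msg, "'g' must have one value per bin")
  if (any(object@g < 0)) msg <- c(msg, "g(r) must be non-negative")
  if (!.isUniform(object@r)) msg <- c(msg, "bins must be uniform")
  if (length(msg)) msg else TRUE
})

#' ColloidRecord: sticky-sphere interaction summary for one pair
#'
#' One row of a colloid-theory interaction table: effective radii, hard-sphere
#' volume, second virial coefficient, Baxter stickiness parameter and
#' dissociation constant.
#'
#' @slot pair character pair label.
#' @slot a1,a2 effective sphere radii, Angstrom (`a2` is `NA` for homotypic
#'   pairs).
#' @slot vhs hard-sphere volume, cubic Angstrom.
#' @slot b2 second virial coefficient, cubic Angstrom.
#' @slot rmax upper integration limit used for B2, Angstrom.
#' @slot tauB Baxter stickiness parameter (dimensionless).
#' @slot kd dissociation constant, mM.
#' @slot referenceVolume volume used to convert tauB to KD, cubic Angstrom.
#' @export
setClass("ColloidRecord",
  representation(pair = "character", a1 = "numeric", a2 = "numeric",
                 vhs = "numeric", b2 = "numeric", rmax = "numeric",
                 tauB = "numeric", kd = "numeric", referenceVolume = "numeric")
)

setValidity("ColloidRecord", function(object) {
  msg <- character()
  if (object@vhs <= 0) msg <- c(msg, "'vhs' must be positive")
  if (!is.na(object@tauB) && object@tauB <= 0)
    msg <- c(msg, "'tauB' must be positive when defined")
  if (!is.na(object@kd) && object@kd <= 0)
    msg <- c(msg, "'kd' must be positive when defined")
  if (length(msg)) msg else TRUE
})

#' ModelFitResult: fitted concentration-dependence model
#'
#' @slot model one of `"einstein"`, `"quadratic"`, `"mooney"`, `"cluster_t"`,
#'   `"cluster_r"`.
#' @slot parameters named numeric of fitted parameters (may be empty for the
#'   parameter-free Einstein reference).
#' @slot se named numeric of parameter standard errors.
#' @slot residual residual sum of squares.
#' @export
setClass("ModelFitResult",
  representation(model = "character", parameters = "numeric", se = "numeric",
                 residual = "numeric")
)

setValidity("ModelFitResult", function(object) {
  ok <- c("einstein", "quadratic", "mooney", "cluster_t", "cluster_r")
  if (!object@model %in% ok)
    return(sprintf("'model' must be one of: %s", paste(ok, collapse = ", ")))
  TRUE
})

## ---------------------------------------------------------------------------
## Ground truth and configuration
## ---------------------------------------------------------------------------

#' GroundTruth: generating parameters of a synthetic artifact
#'
#' Every synthetic generator attaches one of these to its output so that
#' estimator tests can compare recovered values against the truth.
#'
#' @slot generator name of the generator that produced the artifact.
#' @slot parameters named list of true parameters (units as documented by
#'   the generator).
#' @slot seed integer seed used.
#' @export
setClass("GroundTruth",
  representation(generator = "character", parameters = "list", seed = "numeric")
)

GroundTruth <- function(generator, parameters, seed) {
  new("GroundTruth", generator = generator, parameters = parameters,
      seed = as.numeric(seed))
}

#' AnalysisConfig: pipeline defaults and physical constants
#'
#' Central configuration record.  Defaults reproduce the analysis conditions
#' used throughout the package: temperature 298 K, 400 ns equilibration
#' discard, 2-10 ns MSD fit window, 0-20 ns rotational fit window, 5 Angstrom
#' molecular / 7 Angstrom residue contact cutoffs, the 0.334/0.890 cP
#' water-model viscosity rescaling pair, and 1430 g/L per unit volume
#' fraction for concentration conversion.
#'
#' @slot temperature K.
#' @slot equilibrationCut ns discarded from the start of each trajectory.
#' @slot msdWindow ns, `c(lower, upper)` lag window for the MSD slope fit.
#' @slot rotationalWindow ns, lag window for the orientation ACF fit.
#' @slot contactCutoff Angstrom, heavy-atom molecular contact cutoff.
#' @slot residueCutoff Angstrom, crowder-atom-to-C-alpha residue cutoff.
#' @slot modelViscosity cP, viscosity of the simulation water model.
#' @slot referenceViscosity cP, experimental reference viscosity.
#' @slot concentrationCoefficient g/L per unit volume fraction.
#' @slot seed default random seed.
#' @export
setClass("AnalysisConfig",
  representation(temperature = "numeric", equilibrationCut = "numeric",
                 msdWindow = "numeric", rotationalWindow = "numeric",
                 contactCutoff = "numeric", residueCutoff = "numeric",
                 modelViscosity = "numeric", referenceViscosity = "numeric",
                 concentrationCoefficient = "numeric", seed = "numeric")
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (object@temperature <= 0) msg <- c(msg, "'temperature' must be positive")
  if (object@equilibrationCut < 0)
    msg <- c(msg, "'equilibrationCut' must be non-negative")
  for (w in c("msdWindow", "rotationalWindow")) {
    win <- slot(object, w)
    if (length(win) != 2L || win[1] >= win[2] || win[1] < 0)
      msg <- c(msg, sprintf("'%s' must be c(lower, upper) with 0 <= lower < upper", w))
  }
  if (object@contactCutoff <= 0 || object@residueCutoff <= 0)
    msg <- c(msg, "contact cutoffs must be positive")
  if (object@modelViscosity <= 0 || object@referenceViscosity <= 0)
    msg <- c(msg, "rescaling viscosities must be positive")
  if (object@concentrationCoefficient <= 0)
    msg <- c(msg, "'concentrationCoefficient' must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname AnalysisConfig-class
#' @param temperature,equilibrationCut,msdWindow,rotationalWindow,contactCutoff,residueCutoff,modelViscosity,referenceViscosity,concentrationCoefficient,seed
#'   see the class slots.
#' @return An [AnalysisConfig-class] object.
#' @export
analysisConfig <- function(temperature = 298, equilibrationCut = 400,
                           msdWindow = c(2, 10), rotationalWindow = c(0, 20),
                           contactCutoff = 5, residueCutoff = 7,
                           modelViscosity = 0.334, referenceViscosity = 0.890,
                           concentrationCoefficient = 1430, seed = 1) {
  new("AnalysisConfig", temperature = temperature,
      equilibrationCut = equilibrationCut, msdWindow = msdWindow,
      rotationalWindow = rotationalWindow, contactCutoff = contactCutoff,
      residueCutoff = residueCutoff, modelViscosity = modelViscosity,
      referenceViscosity = referenceViscosity,
      concentrationCoefficient = concentrationCoefficient, seed = seed)
}
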
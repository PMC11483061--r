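#' @rdname accessors
#' @aliases frameTimes,Trajectory-method
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname accessors
setMethod("frameTimes", "PressureSeries", function(x) x@times)

#' @rdname accessors
setMethod("frameTimes", "ContactTimeline", function(x) x@times)

#' @rdname accessors
setMethod("coords", "Trajectory", function(x) x@coords)

#' @rdname accessors
setMethod("boxLength", "Trajectory", function(x) x@box)

#' @rdname accessors
setMethod("particles", "Trajectory", function(x) x@particles)

#' @rdname accessors
setMethod("isWrapped", "Trajectory", function(x) x@wrapped)

#' @rdname accessors
setMethod("groundTruth", "Trajectory", function(x) x@metadata$groundTruth)

#' @rdname accessors
setMethod("groundTruth", "PressureSeries", function(x) x@metadata$groundTruth)

#' @rdname accessors
setMethod("groundTruth", "ContactTimeline", function(x) x@metadata$groundTruth)

#' @rdname accessors
setMethod("tensorSamples", "PressureSeries", function(x) x@tensors)

#' @rdname accessors
setMethod("systemVolume", "PressureSeries", function(x) x@volume)

#' @rdname accessors
setMethod("systemTemperature", "PressureSeries", function(x) x@temperature)

#' @rdname accessors
setMethod("lagTimes", "CorrelationCurve", function(x) x@lag)

#' @rdname accessors
setMethod("lagTimes", "MSDCurve", function(x) x@lag)

#' @rdname accessors
setMethod("lagTimes", "ViscosityCurve", function(x) x@tau)

#' @rdname accessors
setMethod("curveValues", "CorrelationCurve", function(x) x@value)

#' @rdname accessors
setMethod("curveValues", "MSDCurve", function(x) x@msd)

#' @rdname accessors
setMethod("curveValues", "ViscosityCurve", function(x) x@etaMean)

#' @rdname accessors
setMethod("curveSpread", "CorrelationCurve", function(x) x@spread)

#' @rdname accessors
setMethod("curveSpread", "ViscosityCurve", function(x) x@etaSD)

#' @rdname accessors
#' @param ... unused.
setMethod("estimate", "ViscosityEstimate", function(x, ...) x@eta)

## -- dimensions -------------------------------------------------------------

#' Number of frames / particles / molecules in a Trajectory
#'
#' @param x a [Trajectory-class].
#' @return integer count.
#' @export
nFrames <- function(x) dim(x@coords)[1]

#' @rdname nFrames
#' @export
nParticles <- function(x) dim(x@coords)[2]

#' @rdname nFrames
#' @export
moleculeIds <- function(x) sort(unique(x@particles$molecule))

## -- discardEquilibration ---------------------------------------------------

.dropBefore <- function(times, tCut) {
  if (tCut < 0) stop("'tCut' must be non-negative")
  if (tCut > times[length(times)])
    stop(sprintf("'tCut' (%g ns) is beyond the final time (%g ns)",
                 tCut, times[length(times)]))
  keep <- which(times >= tCut)
  if (!length(keep)) stop("no samples remain after discarding equilibration")
  keep
}

#' @rdname discardEquilibration
setMethod("discardEquilibration", "Trajectory", function(x, tCut) {
  keep <- .dropBefore(x@times, tCut)
  initialize(x, times = x@times[keep] - x@times[keep[1]],
             coords = x@coords[keep, , , drop = FALSE], box = x@box[keep])
})

#' @rdname discardEquilibration
setMethod("discardEquilibration", "PressureSeries", function(x, tCut) {
  keep <- .dropBefore(x@times, tCut)
  initialize(x, times = x@times[keep] - x@times[keep[1]],
             tensors = x@tensors[keep, , drop = FALSE])
})

## -- show -------------------------------------------------------------------

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf("Trajectory: %d frames x %d particles (%d molecules)\n",
              d[1], d[2], length(unique(object@particles$molecule))))
  cat(sprintf("  time span %.4g-%.4g ns, box L = %.4g A, %s\n",
              object@times[1], object@times[d[1]], mean(object@box),
              if (object@wrapped) "wrapped" else "unwrapped"))
  if (!is.null(object@metadata$groundTruth))
    cat(sprintf("  synthetic (%s)\n", object@metadata$groundTruth@generator))
})

setMethod("show", "PressureSeries", function(object) {
  n <- length(object@times)
  cat(sprintf(paste0("PressureSeries: %d samples, dt = %.4g ns, ",
                     "V = %.4g A^3, T = %g K\n"),
              n, if (n > 1) object@times[2] - object@times[1] else NA_real_,
              object@volume, object@temperature))
})

setMethod("show", "CorrelationCurve", function(object) {
  cat(sprintf("CorrelationCurve: %d lags in [%.4g, %.4g]\n",
              length(object@lag), min(object@lag), max(object@lag)))
})

setMethod("show", "MSDCurve", function(object) {
  cat(sprintf("MSDCurve (%s): %d lags up to %.4g ns, MSD max %.4g A^2\n",
              object@selection, length(object@lag), max(object@lag),
              max(object@msd)))
})

setMethod("show", "ViscosityCurve", function(object) {
  cat(sprintf("ViscosityCurve: %d lags up to %.4g ps, %d trajectories\n",
              length(object@tau), max(object@tau), ncol(object@etaRuns)))
  i <- length(object@tau)
  cat(sprintf("  eta(tau_max) = %.4g +/- %.4g cP\n",
              object@etaMean[i], object@etaSD[i]))
})

setMethod("show", "ViscosityEstimate", function(object) {
  cat(sprintf("ViscosityEstimate: eta = %.4g +/- %.4g cP (tau_max = %g ps)\n",
              object@eta, object@uncertainty, object@tauMax))
})

setMethod("show", "TransportEstimate", function(object) {
  unit <- if (object@kind == "translational") "A^2/ns" else "1/ns"
  cat(sprintf("TransportEstimate (%s):\n", object@kind))
  cat(sprintf("  raw (PBC)      %.6g %s\n", object@raw, unit))
  cat(sprintf("  PBC-corrected  %.6g %s\n", object@pbcCorrected, unit))
  cat(sprintf("  rescaled       %.6g %s\n", object@rescaled, unit))
})

setMethod("show", "RotationalFit", function(object) {
  cat(sprintf(paste0("RotationalFit (%s): w = %.3g, tau1 = %.4g ns, ",
                     "tau2 = %.4g ns\n  tau = %.4g ns, Dr = %.4g /ns\n"),
              object@method, object@w, object@tau1, object@tau2,
              object@tau, object@Dr))
})

setMethod("show", "HydrodynamicRadius", function(object) {
  cat(sprintf("HydrodynamicRadius: Rh(trans) = %.4g A, Rh(rot) = %.4g A\n",
              object@translational, object@rotational))
})

setMethod("show", "SurvivalFit", function(object) {
  cat("SurvivalFit (triple exponential):\n")
  cat(sprintf("  tau     = %s ns\n",
              paste(signif(object@tau, 4), collapse = ", ")))
  cat(sprintf("  weights = %s\n",
              paste(signif(object@weights, 4), collapse = ", ")))
  if (object@degenerate) cat("  (degenerate: duplicated time constants)\n")
})

setMethod("show", "ContactTimeline", function(object) {
  cat(sprintf("ContactTimeline: %d pairs x %d frames, %.1f%% in contact\n",
              nrow(object@pairs), length(object@times),
              100 * mean(object@states)))
})

setMethod("show", "ClusterReport", function(object) {
  cat(sprintf(paste0("ClusterReport (probe molecule %d): %d frames\n",
                     "  direct partners     %.3g (time average)\n",
                     "  in-cluster partners %.3g (time average)\n"),
              object@probe, length(object@times), mean(object@direct),
              mean(object@inCluster)))
})

setMethod("show", "ConvergenceSeries", function(object) {
  cat(sprintf("ConvergenceSeries: window %g ns, max Z = %.3g at t = %.4g ns\n",
              object@window, max(object@z), object@times[which.max(object@z)]))
})

setMethod("show", "RDFCurve", function(object) {
  cat(sprintf("RDFCurve (%s): %d bins up to %.4g A, %d frames\n",
              object@pairSelection, length(object@r), object@rmax,
              object@nFrames))
})

setMethod("show", "ColloidRecord", function(object) {
  cat(sprintf("ColloidRecord (%s):\n", object@pair))
  cat(sprintf("  a1 = %.4g A, a2 = %s A, VHS = %.6g A^3\n", object@a1,
              if (is.na(object@a2)) "-" else sprintf("%.4g", object@a2),
              object@vhs))
  cat(sprintf("  B2 = %.6g A^3, tauB = %.4g, KD = %.4g mM\n",
              object@b2, object@tauB, object@kd))
})

setMethod("show", "ModelFitResult", function(object) {
  cat(sprintf("ModelFitResult (%s):", object@model))
  if (length(object@parameters)) {
    cat("\n")
    for (nm in names(object@parameters))
      cat(sprintf("  %s = %.5g (se %.3g)\n", nm, object@parameters[[nm]],
                  if (nm %in% names(object@se)) object@se[[nm]] else NA_real_))
  } else cat(" no free parameters\n")
  cat(sprintf("  residual sum of squares %.5g\n", object@residual))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth (%s, seed %g): %s\n", object@generator,
              object@seed,
              paste(names(object@parameters), collapse = ", ")))
})

#' Extract fitted parameters
#'
#' @param x a [ModelFitResult-class], [SurvivalFit-class],
#'   [RotationalFit-class] or [GroundTruth-class].
#' @return Named numeric vector (or list for `GroundTruth`).
#' @export
fittedParameters <- function(x) {
  if (is(x, "ModelFitResult")) return(x@parameters)
  if (is(x, "SurvivalFit"))
    return(c(w1 = x@weights[1], w2 = x@weights[2], w3 = x@weights[3],
             tau1 = x@tau[1], tau2 = x@tau[2], tau3 = x@tau[3]))
  if (is(x, "RotationalFit"))
    return(c(w = x@w, tau1 = x@tau1, tau2 = x@tau2, tau = x@tau, Dr = x@Dr))
  if (is(x, "GroundTruth")) return(x@parameters)
  stop("no fitted parameters for this class")
}

#' Coerce a ColloidRecord (or list of them) to a data.frame
#'
#' Produces an interaction table with the conventional column order:
#' pair, a1, a2, VHS, B2, rmax, tauB, KD.
#'
#' @param records a [ColloidRecord-class] or list of them.
#' @return `data.frame` with one row per record.
#' @export
colloidTable <- function(records) {
  if (is(records, "ColloidRecord")) records <- list(records)
  do.call(rbind, lapply(records, function(x) {
    data.frame(pair = x@pair, a1 = x@a1, a2 = x@a2, VHS = x@vhs, B2 = x@b2,
               rmax = x@rmax, tauB = x@tauB, KD = x@kd)
  }))
}
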
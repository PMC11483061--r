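#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers; slots are never
#' reached into directly by user code.
#'
#' @param x an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("boxLength", function(x) standardGeneric("boxLength"))

#' @rdname accessors
#' @export
setGeneric("particles", function(x) standardGeneric("particles"))

#' @rdname accessors
#' @export
setGeneric("isWrapped", function(x) standardGeneric("isWrapped"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("tensorSamples", function(x) standardGeneric("tensorSamples"))

#' @rdname accessors
#' @export
setGeneric("systemVolume", function(x) standardGeneric("systemVolume"))

#' @rdname accessors
#' @export
setGeneric("systemTemperature", function(x) standardGeneric("systemTemperature"))

#' @rdname accessors
#' @export
setGeneric("lagTimes", function(x) standardGeneric("lagTimes"))

#' @rdname accessors
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))

#' @rdname accessors
#' @export
setGeneric("curveSpread", function(x) standardGeneric("curveSpread"))

#' @rdname accessors
#' @export
setGeneric("estimate", function(x, ...) standardGeneric("estimate"))

#' Remove the equilibration period
#'
#' Drops every sample earlier than `tCut` ns, matching the convention of
#' discarding the initial non-equilibrium part of a production trajectory
#' (the packaged default is 400 ns).  The remaining times are shifted so the
#' first retained sample is at t = 0.
#'
#' @param x a [Trajectory-class] or [PressureSeries-class].
#' @param tCut equilibration cutoff in ns (non-negative).
#' @return An object of the same class covering times `>= tCut`.
#' @examples
#' traj <- genBrownian(nParticles = 2, DTrue = 1, L = 100, dt = 1,
#'                     nSteps = 9, seed = 1)
#' range(frameTimes(discardEquilibration(traj, 4)))
#' @export
setGeneric("discardEquilibration",
           function(x, tCut) standardGeneric("discardEquilibration"))
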
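## Green-Kubo shear viscosity from ensembles of pressure-tensor series:
## eta(tau) = V/(kB T) * integral_0^tau <P_ab(t) P_ab(0)> dt, with the
## autocorrelation averaged over all nine tensor components (no symmetry
## imposed) and over trajectories, followed by the multi-trajectory
## extrapolation protocol: fit sigma(tau) = A tau^b across trajectories,
## then a sigma-weighted double-exponential fit of the running integral
## whose tau -> infinity plateau is the viscosity estimate.

## Autocovariance of x at lags 0..nLag, unbiased normalization, via FFT.
.acovf <- function(x, nLag) {
  n <- length(x)
  x <- x - mean(x)
  m <- 2^ceiling(log2(2L * n))
  f <- stats::fft(c(x, numeric(m - n)))
  s <- Re(stats::fft(f * Conj(f), inverse = TRUE))[1:(nLag + 1L)] / m
  s / (n - 0:nLag)
}

#' Pressure-tensor autocorrelation across trajectories
#'
#' Computes the autocorrelation function of the pressure-tensor
#' fluctuations, averaged with equal weight over all nine tensor components
#' (each component's own series mean is removed first, which is required for
#' the diagonal components and harmless for the off-diagonal ones) and over
#' trajectories.  Per-trajectory curves are retained for the ensemble
#' uncertainty protocol.
#'
#' @param seriesList list of [PressureSeries-class] objects sharing spacing,
#'   volume and temperature.
#' @param maxLag largest lag, ps.
#' @return A [CorrelationCurve-class] with lag in ps; the metadata holds the
#'   per-trajectory curve matrix and the shared volume/temperature.
#' @export
pressureACF <- function(seriesList, maxLag) {
  if (is(seriesList, "PressureSeries")) seriesList <- list(seriesList)
  if (!length(seriesList)) stop("'seriesList' is empty")
  dts <- vapply(seriesList, function(s) s@times[2] - s@times[1], numeric(1))
  if (max(dts) - min(dts) > 1e-9 * max(dts))
    stop("inconsistent sample spacing across series")
  vols <- vapply(seriesList, systemVolume, numeric(1))
  tmps <- vapply(seriesList, systemTemperature, numeric(1))
  if (length(unique(vols)) != 1L || length(unique(tmps)) != 1L)
    stop("all series must share volume and temperature")
  dtPs <- dts[1] * 1e3
  n <- min(vapply(seriesList, function(s) length(s@times), integer(1)))
  nLag <- floor(maxLag / dtPs)
  if (nLag >= n) stop("'maxLag' must be below the series length")
  perTraj <- vapply(seriesList, function(s) {
    acc <- numeric(nLag + 1L)
    for (k in 1:9) acc <- acc + .acovf(s@tensors[seq_len(n), k], nLag)
    acc / 9
  }, numeric(nLag + 1L))
  perTraj <- matrix(perTraj, nrow = nLag + 1L)
  value <- rowMeans(perTraj)
  spread <- if (ncol(perTraj) > 1L) apply(perTraj, 1L, stats::sd)
            else rep(NA_real_, nLag + 1L)
  CorrelationCurve(lag = (0:nLag) * dtPs, value = value, spread = spread,
                   counts = rep(9 * length(seriesList), nLag + 1L),
                   metadata = list(unit = "ps", perTrajectory = perTraj,
                                   volume = vols[1], temperature = tmps[1]))
}

.cumtrapz <- function(x, y) {
  c(0, cumsum((y[-1] + y[-length(y)]) / 2 * diff(x)))
}

#' Running Green-Kubo viscosity integral
#'
#' Cumulative trapezoid integral of the pressure autocorrelation, scaled by
#' `V/(kB T)` and converted to cP, computed per trajectory and then
#' summarized as an ensemble mean and standard deviation.
#'
#' @param acf a [CorrelationCurve-class] from [pressureACF()].
#' @param volume,temperature system volume (cubic Angstrom) and temperature
#'   (K); taken from the curve metadata when omitted.
#' @return A [ViscosityCurve-class] (lag grid in ps, viscosities in cP).
#' @export
runningViscosity <- function(acf, volume = NULL, temperature = NULL) {
  if (is.null(volume)) volume <- acf@metadata$volume
  if (is.null(temperature)) temperature <- acf@metadata$temperature
  if (is.null(volume) || is.null(temperature))
    stop("'volume' and 'temperature' are required (not found in metadata)")
  pref <- .GK_PREFACTOR(volume, temperature)
  perTraj <- acf@metadata$perTrajectory
  if (is.null(perTraj)) perTraj <- matrix(acf@value, ncol = 1L)
  runs <- apply(perTraj, 2L, function(y) pref * .cumtrapz(acf@lag, y))
  runs <- matrix(runs, nrow = length(acf@lag))
  sd <- if (ncol(runs) > 1L) apply(runs, 1L, stats::sd)
        else rep(NA_real_, nrow(runs))
  new("ViscosityCurve", tau = acf@lag, etaRuns = runs,
      etaMean = rowMeans(runs), etaSD = sd, volume = volume,
      temperature = temperature)
}

#' Power-law fit of the ensemble uncertainty growth
#'
#' Fits `sigma(tau) = A * tau^b` to the cross-trajectory standard deviation
#' of the running viscosity integral by least squares on the log-log scale,
#' quantifying how the Green-Kubo uncertainty grows with integration time.
#'
#' @param curve a [ViscosityCurve-class] built from at least two
#'   trajectories.
#' @param fitRange `c(lower, upper)` lag range in ps (default: all positive
#'   lags).
#' @return Named numeric `c(A, b)`.
#' @export
fitSigmaPowerLaw <- function(curve, fitRange = NULL) {
  if (ncol(curve@etaRuns) < 2L)
    stop("at least two trajectories are needed for the uncertainty fit")
  tau <- curve@tau
  sigma <- curve@etaSD
  keep <- tau > 0 & sigma > 0
  if (!is.null(fitRange)) keep <- keep & tau >= fitRange[1] & tau <= fitRange[2]
  if (sum(keep) < 2L)
    stop("sigma(tau) is degenerate (zero spread) on the fit range")
  fit <- stats::lm(log(sigma[keep]) ~ log(tau[keep]))
  c(A = exp(unname(stats::coef(fit)[1])), b = unname(stats::coef(fit)[2]))
}

## Time-integrated double-exponential: the running integral of a
## two-exponential ACF, with an explicit tau -> infinity plateau
## A * (alpha tau1 + (1 - alpha) tau2).
.etaModel <- function(tau, A, alpha, tau1, tau2) {
  A * (alpha * tau1 * (1 - exp(-tau / tau1)) +
       (1 - alpha) * tau2 * (1 - exp(-tau / tau2)))
}

#' Extrapolate the running viscosity integral to infinite time
#'
#' Fits the time-integrated double-exponential
#' `eta(tau) = A [alpha tau1 (1 - e^(-tau/tau1)) + (1-alpha) tau2 (1 - e^(-tau/tau2))]`
#' to the ensemble-mean running integral up to `tauMax`, weighting residuals
#' by `1/sigma(tau)` from the fitted uncertainty power law, and reports the
#' plateau `A [alpha tau1 + (1-alpha) tau2]` as the viscosity.  The fit is
#' restarted from a grid of log-spaced `(tau1, tau2)` pairs and the lowest
#' weighted residual wins.
#'
#' @param curve a [ViscosityCurve-class].
#' @param sigmaFit named `c(A, b)` from [fitSigmaPowerLaw()]; `NULL` for
#'   unweighted fitting (used for degenerate, zero-spread ensembles).
#' @param tauMax largest lag used, ps.
#' @param nStarts number of multi-start initializations (at least 8).
#' @return A [ViscosityEstimate-class].
#' @export
extrapolateEta <- function(curve, sigmaFit = NULL, tauMax = max(curve@tau),
                           nStarts = 8L) {
  keep <- curve@tau > 0 & curve@tau <= tauMax
  if (sum(keep) < 5L) stop("'tauMax' leaves too few points to fit")
  tau <- curve@tau[keep]
  eta <- curve@etaMean[keep]
  w <- if (is.null(sigmaFit)) rep(1, length(tau))
       else 1 / (sigmaFit[["A"]] * tau^sigmaFit[["b"]])^2
  etaEnd <- eta[length(eta)]

  starts <- expand.grid(
    tau1 = exp(seq(log(min(tau) / 5), log(tauMax), length.out =
                     max(3L, ceiling(sqrt(nStarts))))),
    tau2 = exp(seq(log(min(tau)), log(4 * tauMax), length.out =
                     max(3L, ceiling(sqrt(nStarts))))))
  starts <- starts[starts$tau1 <= starts$tau2, , drop = FALSE]

  best <- NULL
  dat <- data.frame(tau = tau, eta = eta)
  for (i in seq_len(nrow(starts))) {
    a0 <- etaEnd / (0.5 * starts$tau1[i] + 0.5 * starts$tau2[i])
    fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      eta ~ .etaModel(tau, A, alpha, tau1, tau2), data = dat,
      start = list(A = a0, alpha = 0.5, tau1 = starts$tau1[i],
                   tau2 = starts$tau2[i]),
      lower = c(A = 0, alpha = 0, tau1 = min(tau) / 50, tau2 = min(tau) / 50),
      upper = c(A = Inf, alpha = 1, tau1 = Inf, tau2 = Inf),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("double-exponential extrapolation did not converge from any start")
  p <- stats::coef(best$fit)
  plateau <- p[["A"]] * (p[["alpha"]] * p[["tau1"]] +
                         (1 - p[["alpha"]]) * p[["tau2"]])
  iMax <- max(which(keep))
  unc <- if (ncol(curve@etaRuns) > 1L)
    stats::sd(curve@etaRuns[iMax, ]) / sqrt(ncol(curve@etaRuns))
  else NA_real_
  new("ViscosityEstimate", eta = unname(plateau), tauMax = tauMax,
      sigmaPowerLaw = if (is.null(sigmaFit)) c(A = NA_real_, b = NA_real_)
                      else sigmaFit,
      fitParameters = p, uncertainty = unc,
      metadata = list(form = "A*(alpha*tau1*(1-exp(-tau/tau1)) + (1-alpha)*tau2*(1-exp(-tau/tau2)))",
                      residual = best$rss))
}

#' Choose the integration cutoff for the viscosity extrapolation
#'
#' Evaluates the extrapolated viscosity at increasing candidate values of
#' `tauMax` and returns the smallest candidate whose estimate differs from
#' the next candidate's by less than the cross-trajectory uncertainty,
#' i.e. the point where the estimate has stopped changing within statistical
#' error.
#'
#' @param curve a [ViscosityCurve-class].
#' @param sigmaFit uncertainty power law from [fitSigmaPowerLaw()].
#' @param candidateGrid increasing candidate `tauMax` values, ps.
#' @return The selected `tauMax` (ps), with the corresponding
#'   [ViscosityEstimate-class] as attribute `"estimate"`.
#' @export
selectTauMax <- function(curve, sigmaFit, candidateGrid) {
  if (is.unsorted(candidateGrid, strictly = TRUE))
    stop("'candidateGrid' must be strictly increasing")
  ests <- lapply(candidateGrid, function(tm)
    tryCatch(extrapolateEta(curve, sigmaFit, tauMax = tm),
             error = function(e) NULL))
  for (i in seq_len(length(candidateGrid) - 1L)) {
    e1 <- ests[[i]]; e2 <- ests[[i + 1L]]
    if (is.null(e1) || is.null(e2)) next
    tol <- sum(c(e1@uncertainty, e2@uncertainty), na.rm = TRUE)
    if (tol == 0) next
    if (abs(e1@eta - e2@eta) < tol) {
      out <- candidateGrid[i]
      attr(out, "estimate") <- e1
      return(out)
    }
  }
  stop("no candidate tauMax gave a stable estimate; extend the series")
}

#' Relative viscosity with propagated bounds
#'
#' Ratio of a viscosity to a reference viscosity, with conservative extreme
#' bounds `(eta -/+ u) / (etaRef +/- uRef)` from the two uncertainties.
#'
#' @param eta,etaRef viscosity and reference viscosity, cP.
#' @param u,uRef their absolute uncertainties, cP.
#' @return Named numeric `c(ratio, lower, upper)`.
#' @examples
#' relativeViscosity(0.347, 0.334, u = 0.003, uRef = 0.006)
#' @export
relativeViscosity <- function(eta, etaRef, u = 0, uRef = 0) {
  if (etaRef <= 0) stop("'etaRef' must be positive")
  c(ratio = eta / etaRef,
    lower = (eta - u) / (etaRef + uRef),
    upper = (eta + u) / (etaRef - uRef))
}
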
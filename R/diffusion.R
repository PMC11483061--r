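## Translational and rotational diffusion estimators with analytic
## finite-size (periodic-box) corrections, water-model viscosity rescaling,
## and Stokes-Einstein radius analysis.

## Per-frame molecular centers (unweighted mean over the molecule's
## non-solvent particles) as an [nFrames, nMolecules, 3] array.
.moleculeCenters <- function(traj, molecules = NULL) {
  p <- traj@particles
  if (is.null(molecules))
    molecules <- sort(unique(p$molecule[!p$isSolvent]))
  nf <- nFrames(traj)
  com <- array(0, dim = c(nf, length(molecules), 3L))
  for (m in seq_along(molecules)) {
    idx <- which(p$molecule == molecules[m] & !p$isSolvent)
    if (!length(idx)) idx <- which(p$molecule == molecules[m])
    for (d in 1:3)
      com[, m, d] <- rowMeans(traj@coords[, idx, d, drop = FALSE])
  }
  com
}

#' Mean-square displacement of molecular centers
#'
#' Computes `<|r(t + tau) - r(t)|^2>` of molecular centers of mass, averaged
#' over molecules and all sliding time origins, on a grid of lag times.
#' Requires continuous (unwrapped) coordinates.
#'
#' @param traj an unwrapped [Trajectory-class].
#' @param selection molecule ids to include (default: all non-solvent
#'   molecules).
#' @param maxLag largest lag, ns.
#' @param nLags number of lag points; lags are evenly spaced frame
#'   multiples, thinned to at most `nLags` (all lags are used when the grid
#'   is smaller).
#' @return An [MSDCurve-class].
#' @export
computeMSD <- function(traj, selection = NULL, maxLag, nLags = 120L) {
  if (traj@wrapped)
    stop("MSD requires an unwrapped trajectory; call unwrapTrajectory() first")
  com <- .moleculeCenters(traj, selection)
  if (dim(com)[2] == 0L) stop("selection resolves to no molecules")
  nf <- dim(com)[1]
  dt <- traj@times[2] - traj@times[1]
  kMax <- min(nf - 1L, floor(maxLag / dt + 1e-9))
  if (kMax < 1L) stop("'maxLag' is below the frame spacing")
  ks <- unique(round(seq(1L, kMax, length.out = min(nLags, kMax))))
  msd <- vapply(ks, function(k) {
    d <- com[(k + 1L):nf, , , drop = FALSE] - com[1:(nf - k), , , drop = FALSE]
    sum(d * d) / ((nf - k) * dim(com)[2])
  }, numeric(1))
  new("MSDCurve", lag = c(0, ks * dt), msd = c(0, msd),
      selection = if (is.null(selection)) "all"
                  else paste(selection, collapse = ","),
      counts = c(nf, (nf - ks)) * dim(com)[2])
}

#' Diffusion coefficient from the MSD slope
#'
#' Least-squares linear fit of MSD versus lag over a window (2-10 ns by
#' default downstream), returning slope/6.  The intercept is free, so an
#' anomalous short-time offset does not bias the estimate.
#'
#' @param msd an [MSDCurve-class].
#' @param window `c(lower, upper)` lag window, ns.
#' @return Diffusion coefficient under periodic boundary conditions,
#'   square Angstrom per ns.
#' @export
fitDiffusion <- function(msd, window = c(2, 10)) {
  keep <- msd@lag >= window[1] & msd@lag <= window[2]
  if (sum(keep) < 3L) stop("fewer than 3 MSD points inside the fit window")
  fit <- stats::lm(msd@msd[keep] ~ msd@lag[keep])
  unname(stats::coef(fit)[2]) / 6
}

#' Finite-size correction factor for translational diffusion
#'
#' `xi = 2.837297 - 4 pi Rp^2 / (3 L^2)`: the self-interaction constant of a
#' cubic lattice of hydrodynamic images, reduced by a particle-size term.
#'
#' @param Rp particle (protein) radius, Angstrom.
#' @param L cubic box edge, Angstrom.
#' @return Dimensionless xi.
#' @export
xiFactor <- function(Rp, L) {
  if (L <= 0) stop("'L' must be positive")
  2.837297 - 4 * pi * Rp^2 / (3 * L^2)
}

#' Finite-size corrections for diffusion in a periodic box
#'
#' `pbcCorrectTranslational` applies `Dt = Dt_PBC + kB T xi / (6 pi eta L)`;
#' `pbcCorrectRotational` applies `Dr = Dr_PBC + kB T / (6 eta L^3)`.  Both
#' corrections vanish as L grows and are additive in the measured value.
#'
#' @param D,Dr diffusion coefficient measured under periodic boundary
#'   conditions (square Angstrom per ns, or 1/ns for rotation).
#' @param eta solution viscosity, cP.
#' @param L cubic box edge, Angstrom.
#' @param Rp particle radius entering [xiFactor()], Angstrom.
#' @param temperature K.
#' @return Corrected coefficient, same units as the input.
#' @export
pbcCorrectTranslational <- function(D, eta, L, Rp = 0, temperature = 298) {
  if (eta <= 0 || L <= 0) stop("'eta' and 'L' must be positive")
  D + .kT(temperature) * xiFactor(Rp, L) / (6 * pi * eta * L) * .SI_TO_INTERNAL
}

#' @rdname pbcCorrectTranslational
#' @export
pbcCorrectRotational <- function(Dr, eta, L, temperature = 298) {
  if (eta <= 0 || L <= 0) stop("'eta' and 'L' must be positive")
  Dr + .kT(temperature) / (6 * eta * L^3) * .SI_TO_INTERNAL
}

#' Rescale a diffusion coefficient by a viscosity ratio
#'
#' Multiplies by `etaModel / etaExperiment`, correcting for a simulation
#' water model whose viscosity underestimates experiment (defaults: 0.334 cP
#' model vs 0.890 cP reference at 298 K).
#'
#' @param D diffusion coefficient.
#' @param etaModel,etaExperiment the viscosity pair, cP.
#' @return Rescaled coefficient.
#' @examples
#' rescaleByViscosityRatio(622.5)  # 233.6 A^2/ns
#' @export
rescaleByViscosityRatio <- function(D, etaModel = 0.334,
                                    etaExperiment = 0.890) {
  if (etaModel <= 0 || etaExperiment <= 0) stop("viscosities must be positive")
  D * etaModel / etaExperiment
}

#' Assemble a TransportEstimate from a raw PBC value
#'
#' Convenience wrapper chaining the finite-size correction and the
#' water-model viscosity rescaling.
#'
#' @param raw value measured under periodic boundary conditions.
#' @param kind `"translational"` or `"rotational"`.
#' @param eta system viscosity used in the correction, cP.
#' @param L box edge, Angstrom.
#' @param Rp particle radius (translational correction only), Angstrom.
#' @param temperature K.
#' @param etaModel,etaExperiment rescaling viscosity pair, cP.
#' @param se replica standard error, if known.
#' @return A [TransportEstimate-class].
#' @export
transportEstimate <- function(raw, kind = c("translational", "rotational"),
                              eta, L, Rp = 0, temperature = 298,
                              etaModel = 0.334, etaExperiment = 0.890,
                              se = NA_real_) {
  kind <- match.arg(kind)
  corrected <- if (kind == "translational")
    pbcCorrectTranslational(raw, eta, L, Rp, temperature)
  else pbcCorrectRotational(raw, eta, L, temperature)
  new("TransportEstimate", kind = kind, raw = raw, pbcCorrected = corrected,
      rescaled = rescaleByViscosityRatio(corrected, etaModel, etaExperiment),
      se = se,
      inputs = list(eta = eta, L = L, Rp = Rp, temperature = temperature,
                    etaModel = etaModel, etaExperiment = etaExperiment))
}

## Kabsch superposition: proper rotation Q (det +1) minimizing ||X Q - Y||
## for row-wise coordinate matrices X, Y (already centered).
.kabsch <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Rotational autocorrelation of a molecule
#'
#' Implements the random-vector protocol for molecular tumbling: a bundle of
#' random unit vectors is co-rotated with the molecule by applying, per
#' frame, the least-squares (Kabsch, proper-rotation) superposition of the
#' molecule's C-alpha sites onto the first-frame reference.  The
#' second-Legendre autocorrelation `<P2(cos theta(t))>`, averaged over
#' vectors and sliding time origins, is returned.  For isotropic rotational
#' diffusion it decays as `exp(-6 Dr t)`.
#'
#' @param traj a [Trajectory-class].
#' @param molecule molecule id (default: the molecule with C-alpha labels).
#' @param nVectors number of random unit vectors (1000 matches the standard
#'   protocol; the expectation is unchanged by this number, only the
#'   variance).
#' @param maxLag largest lag, ns (default 20).
#' @param seed seed for the random vector directions.
#' @param nLags number of lag points (thinned as in [computeMSD()]).
#' @return A [CorrelationCurve-class] (lag in ns).
#' @export
rotACF <- function(traj, molecule = NULL, nVectors = 1000, maxLag = 20,
                   seed = 1, nLags = 120L) {
  p <- traj@particles
  if (is.null(molecule)) {
    cand <- unique(p$molecule[p$isCalpha])
    if (!length(cand)) stop("no molecule with C-alpha labels")
    molecule <- cand[1]
  }
  idx <- which(p$molecule == molecule & p$isCalpha)
  if (length(idx) < 3L) stop("molecule needs at least 3 C-alpha sites")
  nf <- nFrames(traj)
  ref <- traj@coords[1L, idx, , drop = TRUE]
  ref <- sweep(ref, 2L, colMeans(ref))
  if (svd(ref)$d[2] < 1e-8 * svd(ref)$d[1])
    stop("C-alpha sites are collinear; superposition is degenerate")

  set.seed(.substream(seed, 1L))
  V <- matrix(stats::rnorm(nVectors * 3L), ncol = 3L)
  V <- V / sqrt(rowSums(V^2))

  U <- array(0, dim = c(nf, nVectors, 3L))
  for (f in seq_len(nf)) {
    X <- traj@coords[f, idx, , drop = TRUE]
    X <- sweep(X, 2L, colMeans(X))
    U[f, , ] <- V %*% .kabsch(X, ref)
  }
  dt <- traj@times[2] - traj@times[1]
  kMax <- min(nf - 1L, floor(maxLag / dt + 1e-9))
  ks <- unique(round(seq(1L, kMax, length.out = min(nLags, kMax))))
  vals <- vapply(ks, function(k) {
    dot <- rowSums(U[1:(nf - k), , , drop = FALSE] *
                   U[(k + 1L):nf, , , drop = FALSE], dims = 2L)
    mean(1.5 * dot^2 - 0.5)
  }, numeric(1))
  CorrelationCurve(lag = c(0, ks * dt), value = c(1, vals),
                   counts = c(nf, nf - ks) * nVectors,
                   metadata = list(molecule = molecule, unit = "ns"))
}

#' Double-exponential fit of an orientation autocorrelation
#'
#' Fits `C(t) = w exp(-t/tau1) + (1 - w) exp(-t/tau2)` over the given lag
#' window (0-20 ns by default), then forms the overall relaxation time
#' `tau = (w/tau1 + (1-w)/tau2)^-1` and `Dr = 1/(6 tau)`.
#'
#' @param acf a [CorrelationCurve-class] from [rotACF()].
#' @param window `c(lower, upper)` lag window, ns.
#' @param nStarts multi-start count.
#' @return A [RotationalFit-class] with method `"acf"`.
#' @export
fitRotational <- function(acf, window = c(0, 20), nStarts = 8L) {
  keep <- acf@lag >= window[1] & acf@lag <= window[2]
  if (sum(keep) < 4L) stop("fewer than 4 ACF points inside the fit window")
  dat <- data.frame(t = acf@lag[keep], C = acf@value[keep])
  span <- max(dat$t)
  tauStarts <- exp(seq(log(span / 50), log(2 * span),
                       length.out = max(4L, nStarts %/% 2L)))
  best <- NULL
  for (t1 in tauStarts) for (t2 in tauStarts[tauStarts >= t1]) {
    fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      C ~ w * exp(-t / tau1) + (1 - w) * exp(-t / tau2), data = dat,
      start = list(w = 0.5, tau1 = t1, tau2 = t2),
      lower = c(w = 0, tau1 = span / 1e4, tau2 = span / 1e4),
      upper = c(w = 1, tau1 = Inf, tau2 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("rotational double-exponential fit did not converge")
  p <- stats::coef(best$fit)
  w <- p[["w"]]; tau1 <- p[["tau1"]]; tau2 <- p[["tau2"]]
  if (tau1 > tau2) {  # report the faster component first
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp; w <- 1 - w
  }
  tau <- 1 / (w / tau1 + (1 - w) / tau2)
  new("RotationalFit", w = w, tau1 = tau1, tau2 = tau2, tau = tau,
      Dr = 1 / (6 * tau), method = "acf")
}

#' Rotational relaxation time from an anisotropic diffusion tensor
#'
#' Closed-form overall relaxation time for an anisotropic rotational
#' diffusion tensor with eigenvalues `D1, D2, D3`:
#' `tau = (1/15) [ 1/(D+D1) + 1/(D+D2) + 1/(D+D3) +
#'                 (D1+D2+D3)/(D1 D2 + D2 D3 + D3 D1) ]`
#' with `D = (D1 + D2 + D3)/3`.  In the isotropic limit it reduces to
#' `1/(6 D)`.
#'
#' @param D1,D2,D3 tensor eigenvalues, 1/ns (all positive).
#' @return Relaxation time tau, ns.
#' @export
tauFromTensor <- function(D1, D2, D3) {
  if (any(c(D1, D2, D3) <= 0)) stop("all tensor eigenvalues must be positive")
  D <- (D1 + D2 + D3) / 3
  (1 / (D + D1) + 1 / (D + D2) + 1 / (D + D3) +
     (D1 + D2 + D3) / (D1 * D2 + D2 * D3 + D3 * D1)) / 15
}

#' @rdname tauFromTensor
#' @return `rotationalFitFromTensor` wraps the relaxation time in a
#'   [RotationalFit-class] (method `"tensor"`, single-exponential weights).
#' @export
rotationalFitFromTensor <- function(D1, D2, D3) {
  tau <- tauFromTensor(D1, D2, D3)
  new("RotationalFit", w = 1, tau1 = tau, tau2 = tau, tau = tau,
      Dr = 1 / (6 * tau), method = "tensor")
}

#' Stokes-Einstein hydrodynamic radii
#'
#' Inverts `Dt = kB T / (6 pi eta Rh)` and `Dr = kB T / (8 pi eta Rh^3)` to
#' apparent hydrodynamic radii; for a sphere obeying both laws the two radii
#' agree.  The forward relations are available as `stokesEinsteinDt()` and
#' `stokesEinsteinDr()`.
#'
#' @param Dt translational diffusion coefficient, square Angstrom per ns.
#' @param Dr rotational diffusion coefficient, 1/ns.
#' @param eta viscosity, cP.
#' @param temperature K.
#' @return A [HydrodynamicRadius-class] (radii in Angstrom).
#' @export
hydrodynamicRadii <- function(Dt = NA_real_, Dr = NA_real_, eta,
                              temperature = 298) {
  if (eta <= 0) stop("'eta' must be positive")
  kT <- .kT(temperature) * .SI_TO_INTERNAL
  new("HydrodynamicRadius",
      translational = kT / (6 * pi * eta * Dt),
      rotational = (kT / (8 * pi * eta * Dr))^(1 / 3),
      inputs = list(Dt = Dt, Dr = Dr, eta = eta, temperature = temperature))
}

#' @rdname hydrodynamicRadii
#' @param Rh hydrodynamic radius, Angstrom.
#' @export
stokesEinsteinDt <- function(Rh, eta, temperature = 298) {
  .kT(temperature) * .SI_TO_INTERNAL / (6 * pi * eta * Rh)
}

#' @rdname hydrodynamicRadii
#' @export
stokesEinsteinDr <- function(Rh, eta, temperature = 298) {
  .kT(temperature) * .SI_TO_INTERNAL / (8 * pi * eta * Rh^3)
}

#' Generalized Stokes-Einstein deviation
#'
#' Compares the relative diffusion `D(c)/D0` with the relative fluidity
#' `eta0/eta(c)`.  Their ratio is 1 when the generalized Stokes-Einstein
#' relation `D(c)/D0 = eta0/eta(c)` holds; values below 1 indicate extra
#' slow-down beyond the viscosity increase (e.g. transient cluster
#' formation).
#'
#' @param Dc,D0 diffusion at concentration c and at infinite dilution.
#' @param etaC,eta0 viscosity at concentration c and at infinite dilution.
#' @return Named numeric `c(relativeD, relativeFluidity, deviation)`.
#' @export
stokesEinsteinRatio <- function(Dc, D0, etaC, eta0) {
  if (any(c(Dc, D0, etaC, eta0) <= 0)) stop("all inputs must be positive")
  relD <- Dc / D0
  relF <- eta0 / etaC
  c(relativeD = relD, relativeFluidity = relF, deviation = relD / relF)
}
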
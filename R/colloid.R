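## Colloid-theory interpretation of protein-protein interactions: second
## virial coefficients from center-of-mass radial distribution functions,
## the Baxter adhesive-hard-sphere stickiness parameter, dissociation
## constants, and concentration-dependence models for viscosity and
## cluster-corrected diffusion.

#' Center-of-mass radial distribution function
#'
#' Histograms minimum-image center-of-mass pair distances and normalizes by
#' the ideal-gas shell expectation in the periodic box:
#' `g(r) = V H(r) / (nFrames nPairs 4 pi r^2 dr)`.
#'
#' @param traj a [Trajectory-class].
#' @param groupA,groupB molecule id vectors.  With only `groupA` (default:
#'   all non-solvent molecules) all unordered pairs within the group are
#'   used; with both, all cross pairs.
#' @param binWidth radial bin width, Angstrom.
#' @param rmax histogram upper limit, Angstrom; must be below L/2.
#' @return An [RDFCurve-class].
#' @export
computeRDF <- function(traj, groupA = NULL, groupB = NULL, binWidth = 1,
                       rmax = NULL) {
  p <- traj@particles
  if (is.null(groupA)) groupA <- sort(unique(p$molecule[!p$isSolvent]))
  L <- mean(traj@box)
  cross <- !is.null(groupB)
  if (!cross && length(groupA) < 2L)
    stop("need at least one valid molecule pair")
  if (is.null(rmax)) {
    rmax <- floor(L / 2 / binWidth) * binWidth
    if (rmax >= L / 2) rmax <- rmax - binWidth
  }
  if (rmax >= L / 2) stop("'rmax' must be below L/2")
  mols <- if (cross) c(groupA, groupB) else groupA
  com <- .moleculeCenters(traj, mols)
  nA <- length(groupA)
  nPairs <- if (cross) nA * length(groupB) else nA * (nA - 1L) / 2L
  if (nPairs < 1L) stop("need at least one valid molecule pair")
  nBins <- round(rmax / binWidth)
  breaks <- seq(0, rmax, length.out = nBins + 1L)
  H <- numeric(nBins)
  nf <- dim(com)[1]
  for (f in seq_len(nf)) {
    X <- matrix(com[f, seq_len(nA), ], ncol = 3L)
    Y <- if (cross) matrix(com[f, -seq_len(nA), ], ncol = 3L) else X
    d2 <- .minImageDist2(X, Y, traj@box[f])
    d <- if (cross) sqrt(d2) else sqrt(d2[upper.tri(d2)])
    d <- d[d < rmax]
    if (length(d))
      H <- H + tabulate(findInterval(d, breaks, rightmost.closed = TRUE),
                        nbins = nBins)
  }
  centers <- breaks[-1L] - binWidth / 2
  shell <- 4 * pi * centers^2 * binWidth
  g <- H * L^3 / (nf * nPairs * shell)
  new("RDFCurve", r = centers, g = g,
      pairSelection = if (cross) "cross" else "within",
      nFrames = nf, rmax = rmax)
}

#' Second virial coefficient from a radial distribution function
#'
#' `B2 = 2 pi Integral (1 - g(r)) r^2 dr` integrated to `rmax` (the upper
#' limit is chosen per pair, typically just past the first RDF peak).  The
#' unsampled hard-core region below the first bin center r0 contributes
#' analytically as `2 pi r0^3 / 3` (g = 0 there); the sampled region is
#' integrated by the trapezoid rule.
#'
#' @param rdf an [RDFCurve-class].
#' @param rmax integration limit, Angstrom (default: the curve's range).
#' @return B2 in cubic Angstrom (negative for net attraction).
#' @export
b2FromRDF <- function(rdf, rmax = rdf@rmax) {
  if (rmax > max(rdf@r) + (rdf@r[2] - rdf@r[1]) / 2)
    stop("'rmax' is beyond the sampled RDF grid")
  keep <- rdf@r <= rmax
  r <- rdf@r[keep]
  y <- 2 * pi * (1 - rdf@g[keep]) * r^2
  core <- 2 * pi * r[1]^3 / 3
  core + sum((y[-1] + y[-length(y)]) / 2 * diff(r))
}

#' Hard-sphere interaction volume
#'
#' Homotypic pairs: `VHS = (4/3) pi a^3`, the volume of a sphere of radius
#' `a`.  Heterotypic pairs: `VHS = (2 pi / 12) (a1 + a2)^3`, built from the
#' contact distance of two unequal spheres.  The heterotypic form reduces to
#' the homotypic one when `a1 = a2`.
#'
#' @param a1 first radius, Angstrom.
#' @param a2 second radius, Angstrom, or `NA` for a homotypic pair.
#' @return VHS in cubic Angstrom.
#' @export
hardSphereVolume <- function(a1, a2 = NA) {
  if (a1 <= 0 || (!is.na(a2) && a2 <= 0)) stop("radii must be positive")
  if (is.na(a2)) 4 / 3 * pi * a1^3 else 2 * pi / 12 * (a1 + a2)^3
}

#' Baxter stickiness parameter from B2
#'
#' Inverts the adhesive-hard-sphere relation `B2 = 4 VHS - VHS / tauB` to
#' `tauB = VHS / (4 VHS - B2)`.  Smaller tauB means stickier particles
#' (1/tauB is a clustering propensity); `B2 = 0` gives the ideal-gas value
#' 0.25.  For `B2 >= 4 VHS` the attraction term is non-positive and tauB is
#' undefined.
#'
#' @param B2 second virial coefficient, cubic Angstrom.
#' @param VHS hard-sphere volume, cubic Angstrom.
#' @return Dimensionless tauB.
#' @examples
#' baxterTau(-18403, 7027)   # 0.151
#' baxterTau(102037, 27920)  # 2.895
#' @export
baxterTau <- function(B2, VHS) {
  if (VHS <= 0) stop("'VHS' must be positive")
  if (B2 >= 4 * VHS)
    stop("B2 >= 4 VHS: no attractive stickiness; tauB undefined/infinite")
  VHS / (4 * VHS - B2)
}

#' Dissociation constant from the Baxter parameter
#'
#' `KD = tauB / Vref`, converted from number density (per cubic Angstrom)
#' to mM via 1 A^-3 = 1.66054e6 mM.  For probe-crowder pairs the reference
#' volume is conventionally the probe's own sphere volume (so that KD
#' compares probe binding across crowders); for crowder-crowder pairs it is
#' the pair's VHS.
#'
#' @param tauB Baxter stickiness parameter.
#' @param referenceVolume reference volume, cubic Angstrom.
#' @return KD in mM.
#' @examples
#' kdFromTau(baxterTau(-18403, 7027), hardSphereVolume(12.07))  # 34.1 mM
#' @export
kdFromTau <- function(tauB, referenceVolume) {
  if (tauB <= 0 || referenceVolume <= 0)
    stop("'tauB' and 'referenceVolume' must be positive")
  tauB / referenceVolume * numberDensityToMillimolar
}

#' Full colloid record for one interaction pair
#'
#' Chains [hardSphereVolume()], [baxterTau()] and [kdFromTau()] into one
#' interaction-table row.
#'
#' @param pair pair label.
#' @param a1,a2 effective radii, Angstrom (`a2 = NA` for homotypic).
#' @param B2 second virial coefficient, cubic Angstrom.
#' @param rmax the B2 integration limit used, Angstrom (bookkeeping only).
#' @param referenceRadius radius whose sphere volume converts tauB to KD;
#'   default `NA` uses the pair's VHS (homotypic convention).
#' @param VHS override the hard-sphere volume (e.g. a printed value);
#'   default computes it from the radii.
#' @return A [ColloidRecord-class].
#' @export
colloidRecord <- function(pair, a1, a2 = NA, B2, rmax = NA_real_,
                          referenceRadius = NA, VHS = NULL) {
  if (is.null(VHS)) VHS <- hardSphereVolume(a1, a2)
  tauB <- tryCatch(baxterTau(B2, VHS), error = function(e) NA_real_)
  refVol <- if (is.na(referenceRadius)) VHS
            else 4 / 3 * pi * referenceRadius^3
  kd <- if (is.na(tauB)) NA_real_ else kdFromTau(tauB, refVol)
  new("ColloidRecord", pair = pair, a1 = a1, a2 = as.numeric(a2), vhs = VHS,
      b2 = B2, rmax = rmax, tauB = tauB, kd = kd, referenceVolume = refVol)
}

#' Bridge between the quadratic viscosity coefficient and tauB
#'
#' The second-order coefficient of the quadratic viscosity model relates to
#' the Baxter parameter as `b = 5.931 + 1.899 / tauB` for adhesive hard
#' spheres; `tauFromViscosityB` inverts this to `tauB = 1.899/(b - 5.931)`
#' and `viscosityBFromTau` is the forward map.
#'
#' @param b quadratic viscosity coefficient (must exceed 5.931).
#' @return tauB.
#' @examples
#' tauFromViscosityB(63.4)  # 0.033
#' @export
tauFromViscosityB <- function(b) {
  if (b <= 5.931)
    stop("b <= 5.931: stickiness term non-positive; tauB undefined")
  1.899 / (b - 5.931)
}

#' @rdname tauFromViscosityB
#' @param tauB Baxter stickiness parameter.
#' @export
viscosityBFromTau <- function(tauB) {
  if (tauB <= 0) stop("'tauB' must be positive")
  5.931 + 1.899 / tauB
}

#' Concentration / volume-fraction conversion
#'
#' `phi = c / coefficient` with the default density-like coefficient
#' 1430 g/L per unit volume fraction (from fitting concentration against
#' volume fraction for protein solutions).
#'
#' @param c mass concentration, g/L.
#' @param phi volume fraction.
#' @param coefficient g/L per unit volume fraction.
#' @return Volume fraction (or concentration for the inverse).
#' @export
concToPhi <- function(c, coefficient = 1430) {
  if (any(c < 0)) stop("'c' must be non-negative")
  c / coefficient
}

#' @rdname concToPhi
#' @export
phiToConc <- function(phi, coefficient = 1430) phi * coefficient

#' Evaluate a relative-viscosity model
#'
#' `einstein`: `1 + 2.5 phi` (hard spheres, no free parameter).
#' `quadratic`: `1 + 2.5 phi + b phi^2`.
#' `mooney`: `exp(S phi / (1 - K phi))` with intrinsic viscosity S and
#' self-crowding factor K (pole at `K phi = 1`).
#'
#' @param model model name.
#' @param phi volume fractions.
#' @param parameters named list/vector (`b`, or `S` and `K`; ignored for
#'   einstein).
#' @return Relative viscosity values.
#' @export
evalViscosityModel <- function(model = c("einstein", "quadratic", "mooney"),
                               phi, parameters = NULL) {
  model <- match.arg(model)
  parameters <- as.list(parameters)
  switch(model,
    einstein = 1 + 2.5 * phi,
    quadratic = 1 + 2.5 * phi + parameters$b * phi^2,
    mooney = {
      if (any(parameters$K * phi >= 1))
        stop("Mooney pole: K * phi >= 1 inside the grid")
      exp(parameters$S * phi / (1 - parameters$K * phi))
    })
}

#' Fit a relative-viscosity model to concentration data
#'
#' Least-squares fit of the chosen model (see [evalViscosityModel()]).  The
#' Einstein reference has no free parameters and reports only the residual;
#' the quadratic model is linear in `b` and solved in closed form; the
#' Mooney model is fitted by bounded Levenberg-Marquardt keeping the pole
#' `K phi = 1` outside the data range.
#'
#' @param phi volume fractions.
#' @param etaR relative viscosities.
#' @param model `"einstein"`, `"quadratic"` or `"mooney"`.
#' @param weights optional least-squares weights.
#' @return A [ModelFitResult-class].
#' @export
fitViscosityModel <- function(phi, etaR, model = c("einstein", "quadratic",
                                                   "mooney"),
                              weights = NULL) {
  model <- match.arg(model)
  nFree <- c(einstein = 0L, quadratic = 1L, mooney = 2L)[[model]]
  if (length(phi) < nFree + 1L)
    stop("need at least (number of free parameters + 1) data points")
  if (is.null(weights)) weights <- rep(1, length(phi))
  if (model == "einstein") {
    res <- sum(weights * (etaR - (1 + 2.5 * phi))^2)
    return(new("ModelFitResult", model = model, parameters = numeric(0),
               se = numeric(0), residual = res))
  }
  if (model == "quadratic") {
    y <- etaR - 1 - 2.5 * phi
    fit <- stats::lm(y ~ 0 + I(phi^2), weights = weights)
    b <- unname(stats::coef(fit))
    ## suppressed: lm warns on exact (zero-residual) recovery data
    se <- unname(suppressWarnings(sqrt(diag(stats::vcov(fit)))))
    return(new("ModelFitResult", model = model, parameters = c(b = b),
               se = c(b = se), residual = sum(weights * stats::residuals(fit)^2)))
  }
  kMax <- 0.999 / max(phi[phi > 0])
  sw <- sqrt(weights)
  resFn <- function(p) sw * (etaR - exp(p[1] * phi / (1 - p[2] * phi)))
  fit <- .lmFit(resFn, starts = list(c(2.5, 0.1), c(1, 0.01),
                                     c(5, kMax / 4)),
                lower = c(0, 0), upper = c(Inf, kMax))
  new("ModelFitResult", model = model,
      parameters = c(S = fit$par[1], K = fit$par[2]),
      se = c(S = fit$se[1], K = fit$se[2]), residual = fit$rss)
}

## Bounded Levenberg-Marquardt with multiple starts; standard errors from
## the Jacobian at the optimum (NA when not estimable, e.g. exact fits on
## a parameter bound).
.lmFit <- function(resFn, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    out <- tryCatch(minpack.lm::nls.lm(
      par = st, fn = resFn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(out)) next
    rss <- sum(out$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(out = out, rss = rss)
  }
  if (is.null(best)) stop("nonlinear fit did not converge from any start")
  se <- tryCatch(summary(best$out)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(best$out$par)))
  list(par = unname(best$out$par), se = unname(se), rss = best$rss)
}

#' Fit the effective-cluster diffusion model
#'
#' Fits `D(phi) = D0 / (etaR(phi) (1 + sigma phi)^p)` with `p = 1/3` for
#' translational and `p = 1` for rotational diffusion; `1 + sigma phi` is
#' interpreted as an effective cluster size, with `sigma = 0` meaning no
#' clustering.  `sigma` is constrained non-negative.  `D0` is either fixed
#' (e.g. from the dilute point) or co-fitted.
#'
#' @param phi volume fractions.
#' @param D diffusion coefficients.
#' @param mode `"translational"` or `"rotational"`.
#' @param etaRModel a fitted [ModelFitResult-class] (quadratic or mooney),
#'   or a `list(model =, parameters =)`, supplying etaR(phi).
#' @param D0 fixed dilute-limit coefficient, or `NULL` to co-fit.
#' @return A [ModelFitResult-class] (model `"cluster_t"` or `"cluster_r"`)
#'   whose parameters are `sigma` (and `D0` when co-fitted); the attribute
#'   `"clusterSize"` reports `1 + sigma phi` on the input grid.
#' @export
fitClusterDiffusion <- function(phi, D, mode = c("translational",
                                                 "rotational"),
                                etaRModel, D0 = NULL) {
  mode <- match.arg(mode)
  pw <- if (mode == "translational") 1 / 3 else 1
  if (is(etaRModel, "ModelFitResult"))
    etaRModel <- list(model = etaRModel@model,
                      parameters = etaRModel@parameters)
  etaR <- evalViscosityModel(etaRModel$model, phi, etaRModel$parameters)
  if (is.null(D0)) {
    resFn <- function(p) D - p[1] / (etaR * (1 + p[2] * phi)^pw)
    fit <- .lmFit(resFn, starts = list(c(max(D), 1), c(max(D), 20),
                                       c(max(D) * 1.2, 0.1)),
                  lower = c(0, 0), upper = c(Inf, Inf))
    pars <- c(sigma = fit$par[2], D0 = fit$par[1])
    ses <- c(sigma = fit$se[2], D0 = fit$se[1])
  } else {
    resFn <- function(p) D - D0 / (etaR * (1 + p[1] * phi)^pw)
    fit <- .lmFit(resFn, starts = list(1, 20, 0.1), lower = 0, upper = Inf)
    pars <- c(sigma = fit$par[1])
    ses <- c(sigma = fit$se[1])
  }
  out <- new("ModelFitResult",
             model = if (mode == "translational") "cluster_t" else "cluster_r",
             parameters = pars, se = ses, residual = fit$rss)
  attr(out, "clusterSize") <- 1 + pars[["sigma"]] * phi
  out
}

#' Characteristic diffusion length
#'
#' Distance scale `sqrt(D tau)` travelled at diffusion coefficient D over a
#' contact survival time tau; comparing it to molecular size indicates
#' whether a contact persists long enough to slow diffusion.
#'
#' @param D diffusion coefficient, square Angstrom per ns.
#' @param tau time scale, ns.
#' @return Length in Angstrom.
#' @examples
#' characteristicDiffusionLength(9, 60)  # ~23 Angstrom
#' @export
characteristicDiffusionLength <- function(D, tau) {
  if (D < 0 || tau < 0) stop("'D' and 'tau' must be non-negative")
  sqrt(D * tau)
}

#' Refit the concentration / volume-fraction coefficient (exploratory)
#'
#' Least-squares slope of concentration against volume fraction through the
#' origin.  Exploratory helper only: the packaged conversion constant
#' (1430 g/L) is a fixed configuration value and is not refitted by any
#' pipeline stage.
#'
#' @param c concentrations, g/L.
#' @param phi volume fractions.
#' @return Fitted coefficient, g/L per unit volume fraction.
#' @export
fitConcentrationCoefficient <- function(c, phi) {
  unname(stats::coef(stats::lm(c ~ 0 + phi)))
}
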
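## Contact detection, cluster decomposition, contact-survival kinetics and
## convergence diagnostics.  Cutoff comparisons are strict (<), matching the
## "minimum distance of less than 5 A" convention; boundary frames therefore
## depend on this choice and it is applied uniformly.

## Squared minimum-image distances between row sets X [n1 x 3] and
## Y [n2 x 3] in a cubic box of edge L.
.minImageDist2 <- function(X, Y, L) {
  d2 <- matrix(0, nrow(X), nrow(Y))
  for (d in 1:3) {
    dx <- outer(X[, d], Y[, d], "-")
    dx <- dx - L * round(dx / L)
    d2 <- d2 + dx * dx
  }
  d2
}

#' Molecular contact timeline from a trajectory
#'
#' Two molecules are in contact in a frame when the minimum distance
#' between any of their heavy-atom pairs is strictly below the cutoff
#' (5 Angstrom by default), under the minimum-image convention.  The exact
#' all-pairs distance computation is used.
#'
#' @param traj a [Trajectory-class] with heavy-atom labels.
#' @param cutoff contact cutoff, Angstrom.
#' @param selection molecule ids to include (default: all non-solvent
#'   molecules; at least 2 required).
#' @return A [ContactTimeline-class] over all unordered molecule pairs.
#' @export
contactTimeline <- function(traj, cutoff = 5, selection = NULL) {
  p <- traj@particles
  if (is.null(selection)) selection <- sort(unique(p$molecule[!p$isSolvent]))
  if (length(selection) < 2L)
    stop("selection must resolve to at least 2 molecules")
  heavyIdx <- which(p$isHeavy & p$molecule %in% selection)
  if (!length(heavyIdx)) stop("no heavy atoms in the selection")
  mol <- factor(p$molecule[heavyIdx], levels = selection)
  M <- stats::model.matrix(~ mol - 1)
  nm <- length(selection)
  pairIdx <- which(upper.tri(matrix(0, nm, nm)), arr.ind = TRUE)
  nf <- nFrames(traj)
  states <- matrix(FALSE, nf, nrow(pairIdx))
  cut2 <- cutoff^2
  for (f in seq_len(nf)) {
    X <- traj@coords[f, heavyIdx, , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = 3L)
    A <- .minImageDist2(X, X, traj@box[f]) < cut2
    counts <- crossprod(M, A %*% M)  # heavy-atom contact counts per pair
    states[f, ] <- counts[cbind(pairIdx[, 1], pairIdx[, 2])] > 0
  }
  ContactTimeline(pairs = cbind(selection[pairIdx[, 1]],
                                selection[pairIdx[, 2]]),
                  times = traj@times, states = states,
                  metadata = list(cutoff = cutoff))
}

#' Per-residue crowder contact density
#'
#' For each residue of the probe molecule, counts the heavy atoms of all
#' other molecules strictly within the cutoff (7 Angstrom by default) of
#' the residue's C-alpha position, averaged over frames.  With a list of
#' replica trajectories, replica means and standard errors are reported.
#'
#' @param traj a [Trajectory-class], or a list of replicas.
#' @param probe probe molecule id.
#' @param cutoff residue contact cutoff, Angstrom.
#' @return `data.frame(residue, count, se)`; `se` is `NA` for a single
#'   trajectory.
#' @export
residueContactDensity <- function(traj, probe, cutoff = 7) {
  if (is.list(traj)) {
    per <- lapply(traj, residueContactDensity, probe = probe, cutoff = cutoff)
    counts <- vapply(per, function(x) x$count, numeric(nrow(per[[1]])))
    counts <- matrix(counts, nrow = nrow(per[[1]]))
    return(data.frame(residue = per[[1]]$residue,
                      count = rowMeans(counts),
                      se = apply(counts, 1L, stats::sd) / sqrt(ncol(counts))))
  }
  p <- traj@particles
  caIdx <- which(p$molecule == probe & p$isCalpha)
  if (!length(caIdx)) stop("probe molecule has no C-alpha labels")
  crowderIdx <- which(p$molecule != probe & p$isHeavy)
  nf <- nFrames(traj)
  acc <- numeric(length(caIdx))
  cut2 <- cutoff^2
  for (f in seq_len(nf)) {
    CA <- matrix(traj@coords[f, caIdx, , drop = TRUE], ncol = 3L)
    CR <- matrix(traj@coords[f, crowderIdx, , drop = TRUE], ncol = 3L)
    acc <- acc + rowSums(.minImageDist2(CA, CR, traj@box[f]) < cut2)
  }
  data.frame(residue = p$residue[caIdx], count = acc / nf,
             se = NA_real_)
}

## Connected components over an edge list, as a membership vector.
.components <- function(ids, edges) {
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(edges)) {
    ii <- match(edges[, 1], ids)
    jj <- match(edges[, 2], ids)
    for (e in seq_len(nrow(edges))) {
      ri <- find(ii[e]); rj <- find(jj[e])
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_along(ids), find, integer(1))
}

#' Cluster decomposition of the contact graph
#'
#' `clusterDecomposition` decomposes a single frame of a contact timeline
#' into connected components; `clusterReport` does so for every frame and
#' summarizes, for a probe molecule, the number of direct contact partners
#' (graph neighbors) and in-cluster partners (co-members of the probe's
#' connected component, excluding the probe).
#'
#' @param timeline a [ContactTimeline-class] covering all molecule pairs.
#' @param frame frame index.
#' @param probe probe molecule id.
#' @return `clusterDecomposition`: list with `components` (list of integer
#'   vectors of molecule ids), and if `probe` is given, `direct` and
#'   `inCluster` counts.  `clusterReport`: a [ClusterReport-class].
#' @export
clusterDecomposition <- function(timeline, frame, probe = NULL) {
  ids <- sort(unique(as.vector(timeline@pairs)))
  active <- timeline@pairs[timeline@states[frame, ], , drop = FALSE]
  memb <- .components(ids, active)
  comps <- split(ids, memb)
  names(comps) <- NULL
  out <- list(components = comps)
  if (!is.null(probe)) {
    touches <- (timeline@pairs[, 1] == probe | timeline@pairs[, 2] == probe) &
      timeline@states[frame, ]
    out$direct <- sum(touches)
    mine <- memb[match(probe, ids)]
    out$inCluster <- sum(memb == mine) - 1L
  }
  out
}

#' @rdname clusterDecomposition
#' @param keepComponents store the per-frame component lists (memory-heavy
#'   for long timelines).
#' @export
clusterReport <- function(timeline, probe, keepComponents = FALSE) {
  nf <- length(timeline@times)
  direct <- numeric(nf)
  inCluster <- numeric(nf)
  comps <- if (keepComponents) vector("list", nf) else list()
  for (f in seq_len(nf)) {
    d <- clusterDecomposition(timeline, f, probe)
    direct[f] <- d$direct
    inCluster[f] <- d$inCluster
    if (keepComponents) comps[[f]] <- d$components
  }
  new("ClusterReport", probe = as.integer(probe), times = timeline@times,
      direct = direct, inCluster = inCluster, components = comps)
}

#' Intermittent contact autocorrelation
#'
#' `P(dt) = < delta_i(t) delta_i(t + dt) >` averaged over all molecule pairs
#' (including pairs never in contact) and all sliding time origins, then
#' normalized by `P(0)` so that multi-exponential fits have weights summing
#' to one.  The normalization is recorded in the metadata.
#'
#' For a stationary contact process the correlation decays not to zero but
#' to a plateau (the product of mean contact probabilities), which a pure
#' multi-exponential fit absorbs into its slowest time constant.
#' `subtractPlateau` estimates the plateau empirically from the long-lag
#' tail of the computed window and renormalizes `(P - plateau)/(1 -
#' plateau)`; the estimate is recorded in the metadata.
#'
#' @param timeline a [ContactTimeline-class] with uniform frame spacing.
#' @param maxLag largest lag, ns.
#' @param nLags number of (log-spaced) lag points returned.
#' @param subtractPlateau subtract the empirical long-lag plateau.
#' @param plateauWindow `c(lower, upper)` lag range (ns) averaged for the
#'   plateau estimate; defaults to the last quarter of the lag window.
#' @return A [CorrelationCurve-class]; metadata elements `P0` and `plateau`
#'   hold the unnormalized zero-lag value and the subtracted plateau.
#' @export
contactACF <- function(timeline, maxLag, nLags = 200L,
                       subtractPlateau = FALSE, plateauWindow = NULL) {
  s <- timeline@states
  n <- nrow(s)
  dt <- timeline@times[2] - timeline@times[1]
  kMax <- min(n - 1L, floor(maxLag / dt + 1e-9))
  ## raw product correlation per pair via FFT (no mean removal); first and
  ## second moments across pairs give the cross-pair spread per lag
  m <- 2^ceiling(log2(2L * n))
  acc <- numeric(kMax + 1L)
  acc2 <- numeric(kMax + 1L)
  for (j in seq_len(ncol(s))) {
    x <- as.numeric(s[, j])
    f <- stats::fft(c(x, numeric(m - n)))
    pj <- Re(stats::fft(f * Conj(f), inverse = TRUE))[1:(kMax + 1L)] / m /
      (n - 0:kMax)
    acc <- acc + pj
    acc2 <- acc2 + pj^2
  }
  np <- ncol(s)
  P <- acc / np
  if (P[1] <= 0) stop("no pair is ever in contact (P(0) = 0)")
  se <- if (np > 1L) sqrt(pmax(acc2 / np - P^2, 0) / (np - 1L)) / P[1]
        else rep(NA_real_, kMax + 1L)
  Pn <- P / P[1]
  plateau <- 0
  if (subtractPlateau) {
    if (is.null(plateauWindow)) plateauWindow <- c(0.75, 1) * kMax * dt
    tail <- which((0:kMax) * dt >= plateauWindow[1] &
                  (0:kMax) * dt <= plateauWindow[2])
    if (length(tail) < 2L) stop("'plateauWindow' selects too few lags")
    plateau <- mean(Pn[tail])
    Pn <- (Pn - plateau) / (1 - plateau)
    se <- se / (1 - plateau)
  }
  ks <- unique(round(exp(seq(log(1), log(kMax), length.out = nLags))))
  CorrelationCurve(lag = c(0, ks * dt), value = c(1, Pn[ks + 1L]),
                   spread = c(0, se[ks + 1L]),
                   counts = c(n, n - ks) * np,
                   metadata = list(P0 = P[1], normalized = TRUE,
                                   plateau = plateau, unit = "ns"))
}

## Triple-exponential with softmax weights and log time constants; the
## parameterization keeps the weights on the simplex without constraints.
.survivalModel <- function(t, a1, a2, l1, l2, l3) {
  e <- c(exp(a1), exp(a2), 1)
  w <- e / sum(e)
  w[1] * exp(-t / exp(l1)) + w[2] * exp(-t / exp(l2)) + w[3] * exp(-t / exp(l3))
}

#' Triple-exponential contact survival fit
#'
#' Fits `P(dt) = w1 exp(-dt/tau1) + w2 exp(-dt/tau2) + (1-w1-w2) exp(-dt/tau3)`
#' with weights constrained to the probability simplex and time constants
#' positive, by multi-start Levenberg-Marquardt from fixed log-spaced
#' starting triplets; the lowest-residual solution is returned with time
#' constants sorted in increasing order.  When two fitted constants
#' collapse (ratio below 1.25) the result is flagged as degenerate.
#'
#' @param acf a normalized [CorrelationCurve-class] (e.g. [contactACF()]).
#' @param fitRange `c(lower, upper)` lag range, ns (default: all positive
#'   lags).
#' @param nStarts number of starting triplets.
#' @param weighted use inverse-variance weights from the curve's cross-pair
#'   spread.  Off by default: with strongly correlated residuals the
#'   weights concentrate on the short-lag region and can starve the
#'   intermediate time constant.
#' @return A [SurvivalFit-class].
#' @export
fitSurvival <- function(acf, fitRange = NULL, nStarts = 12L,
                        weighted = FALSE) {
  keep <- acf@lag > 0
  if (!is.null(fitRange))
    keep <- keep & acf@lag >= fitRange[1] & acf@lag <= fitRange[2]
  if (sum(keep) < 9L) stop("at least 9 points are required for the fit")
  dat <- data.frame(t = acf@lag[keep], P = acf@value[keep])
  w <- rep(1, nrow(dat))
  sp <- acf@spread[keep]
  if (weighted && !anyNA(sp) && any(sp > 0))
    w <- 1 / pmax(sp, max(sp[sp > 0]) * 1e-3)^2
  span <- range(dat$t)
  grid <- exp(seq(log(span[1]), log(span[2]), length.out = 3L + nStarts %/% 4L))
  starts <- utils::combn(seq_along(grid), 3L)
  best <- NULL
  for (i in seq_len(min(ncol(starts), nStarts * 2L))) {
    taus <- grid[starts[, i]]
    fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      P ~ .survivalModel(t, a1, a2, l1, l2, l3), data = dat,
      start = list(a1 = 0, a2 = 0, l1 = log(taus[1]), l2 = log(taus[2]),
                   l3 = log(taus[3])),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 300))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("triple-exponential survival fit did not converge from any start")
  p <- stats::coef(best$fit)
  e <- c(exp(p[["a1"]]), exp(p[["a2"]]), 1)
  w <- e / sum(e)
  tau <- exp(c(p[["l1"]], p[["l2"]], p[["l3"]]))
  ord <- order(tau)
  tau <- tau[ord]; w <- w[ord]
  degenerate <- any(tau[-1] / tau[-3] < 1.25)
  new("SurvivalFit", weights = unname(w), tau = unname(tau),
      residual = best$rss, degenerate = degenerate)
}

## SEM by block averaging: split into nBlocks contiguous blocks, SEM of
## block means.  Standard choice for autocorrelated series.
.blockSEM <- function(x, nBlocks = 5L) {
  n <- length(x)
  if (n < nBlocks) return(stats::sd(x) / sqrt(n))
  idx <- cut(seq_len(n), nBlocks, labels = FALSE)
  bm <- tapply(x, idx, mean)
  stats::sd(bm) / sqrt(nBlocks)
}

#' Windowed Z-score convergence diagnostic
#'
#' For each start time t, compares the short-time average of an observable
#' over `[t, t + window]` with the long-time average over `[t, tmax]`:
#' `Z(t) = |a_short - a_long| / (SEM(a_short) + SEM(a_long))`, with standard
#' errors from block averaging (5 blocks per interval).  A Z-score around 1
#' indicates the two averages agree within one standard error, i.e. the
#' series has equilibrated.
#'
#' @param times sample times, ns (uniform spacing).
#' @param values observable values (e.g. probe contact counts).
#' @param window short-average window length, ns (default 400).
#' @param nEval maximum number of evaluated start times.
#' @return A [ConvergenceSeries-class].
#' @export
convergenceZscore <- function(times, values, window = 400, nEval = 200L) {
  if (length(values) != length(times)) stop("times/values length mismatch")
  tmax <- times[length(times)]
  if (window >= tmax - times[1]) stop("'window' must be shorter than the series")
  startMax <- tmax - window
  cand <- which(times <= startMax)
  starts <- cand[unique(round(seq(1L, length(cand),
                                  length.out = min(nEval, length(cand)))))]
  z <- shortMean <- longMean <- numeric(length(starts))
  for (i in seq_along(starts)) {
    t0 <- times[starts[i]]
    short <- values[times >= t0 & times <= t0 + window]
    long <- values[times >= t0]
    shortMean[i] <- mean(short)
    longMean[i] <- mean(long)
    num <- abs(shortMean[i] - longMean[i])
    den <- .blockSEM(short) + .blockSEM(long)
    z[i] <- if (num == 0) 0 else num / den
  }
  new("ConvergenceSeries", times = times[starts], z = z, window = window,
      shortMean = shortMean, longMean = longMean)
}
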
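---
title: "Transport coefficients in crowded protein solutions: models and estimators"
author: "crowdedTransport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transport coefficients in crowded protein solutions: models and estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`crowdedTransport` implements the analysis layer of a molecular-dynamics
study of diffusion and viscosity in crowded protein solutions: shear
viscosity from equilibrium pressure-tensor fluctuations (Green-Kubo),
translational and rotational diffusion with finite-size corrections and
water-model rescaling, contact and cluster kinetics, and a colloid-theory
interpretation of protein-protein interactions (second virial coefficients,
Baxter stickiness, dissociation constants, Mooney-type viscosity laws and
effective-cluster diffusion models).  Running the molecular dynamics itself
is out of scope; the package consumes trajectories, pressure-tensor time
series and concentration tables, and ships seeded synthetic generators with
recorded ground truth so that every estimator can be validated by parameter
recovery.

All lengths are in Angstrom, times in ns (lag grids of the viscosity module
in ps), viscosities in cP, pressures in bar, temperatures in K.  The
conversion constants (Boltzmann constant, the 1 A^-3 = 1.66054e6 mM number
density conversion) live in a single file so each physical formula is
written exactly once in one unit convention.  Boxes are restricted to
cubic: every finite-size correction used here is derived for cubic
periodicity, and the loaders reject non-cubic cells rather than silently
averaging edge lengths.

# Green-Kubo viscosity

The shear viscosity is the time integral of the equilibrium autocorrelation
of the pressure tensor,

$$\eta(\tau) = \frac{V}{k_B T}\int_0^\tau \langle P_{\alpha\beta}(t)\,
P_{\alpha\beta}(0)\rangle\, dt ,$$

accumulated by `pressureACF()` and `runningViscosity()`.  All nine tensor
components enter with equal weight and without imposing symmetry; each
component's own series mean is removed first, which is required for the
diagonal components (they carry the mean pressure) and harmless for the
off-diagonal ones.  Integration uses the trapezoid rule, adequate for the
dense (few fs) sampling this estimator is designed for.

A single finite trajectory never shows a clean plateau, so the package
follows the multi-trajectory protocol: the running integral is evaluated
per trajectory, the cross-trajectory standard deviation is fitted to a
power law $\sigma(\tau) = A\tau^b$ (`fitSigmaPowerLaw()`), and the ensemble
mean $\eta(\tau)$ is fitted with weights $1/\sigma(\tau)$ up to a cutoff
$\tau_{max}$ by a double-exponential whose time-integrated form makes the
$\tau\to\infty$ plateau an explicit parameter combination:

$$\eta(\tau) = A\left[\alpha\tau_1(1-e^{-\tau/\tau_1}) +
(1-\alpha)\tau_2(1-e^{-\tau/\tau_2})\right],\qquad
\eta_\infty = A[\alpha\tau_1 + (1-\alpha)\tau_2].$$

The literature protocol does not print its double-exponential functional
form; this integrated form is the natural choice because it is the exact
running integral of a two-exponential ACF, and it is recorded in the
estimate's metadata.  The fit is restarted from a grid of log-spaced
$(\tau_1, \tau_2)$ pairs (at least 8 starts) and ties are broken by the
lowest weighted residual.  `selectTauMax()` implements the stopping rule:
the smallest candidate $\tau_{max}$ whose estimate differs from the next
candidate's by less than the cross-trajectory uncertainty.

One numerical caveat is documented rather than hidden: removing each
component's empirical mean biases the integrated autocorrelation downward
by a term of order $\tau_{max}/T_{traj}$ relative to the truth.  The
weighted extrapolation concentrates statistical weight at small $\tau$
where this bias is negligible, which is why the pipeline recovers the
analytic viscosity of Ornstein-Uhlenbeck ensembles to better than a percent
while the raw running integral at large $\tau$ can sit several percent low.

# Translational diffusion

`computeMSD()` computes center-of-mass mean-square displacements over all
sliding time origins (centers are unweighted means over each molecule's
non-solvent particles, since particle masses are not part of the data
model).  The diffusion coefficient is the fitted slope over a lag window,
divided by six; the default 2-10 ns window avoids short-time anomalous
behavior and poor long-lag statistics.  The intercept is left free so an
anomalous offset does not bias the slope.  Unwrapping
(`unwrapTrajectory()`) is minimum-image continuation, exact whenever true
per-frame displacements stay below half the box edge; violations are
reported with the offending particle and frame rather than guessed.

Periodic-boundary self-interaction suppresses diffusion; the additive
correction is

$$D_t = D_t^{PBC} + \frac{k_B T\,\xi}{6\pi\eta L},\qquad
\xi = 2.837297 - \frac{4\pi R_p^2}{3L^2},$$

with the box edge $L$, solution viscosity $\eta$ and a particle radius
$R_p$.  The source protocol does not define $R_p$ precisely; the package
accepts it as an input and by convention uses the radius of the sphere with
the molecule's volume, the same size convention as the colloid module, with
$R_p = 0$ as the conservative default.  Simulations with an underestimating
water model are rescaled by the model/experiment viscosity ratio
(`rescaleByViscosityRatio()`, default 0.334/0.890 cP at 298 K).  For NPT
data with per-frame box fluctuations the correction is applied with the
mean edge length; the data model keeps per-frame edges so other reductions
remain possible.

# Rotational diffusion

`rotACF()` implements the random-vector protocol: a bundle of random unit
vectors (1000 by default; the number affects only the variance) is
co-rotated with the molecule using, per frame, the proper (determinant +1)
least-squares superposition of its C-alpha sites onto the first-frame
reference, unweighted because the protocol specifies none.  The
second-Legendre autocorrelation $\langle P_2(\cos\theta(t))\rangle$ is fit
over 0-20 ns by a double exponential
$C(t) \approx w e^{-t/\tau_1} + (1-w)e^{-t/\tau_2}$, from which

$$\tau = \left(\frac{w}{\tau_1} + \frac{1-w}{\tau_2}\right)^{-1},
\qquad D_r = \frac{1}{6\tau}.$$

The amplitude weights are used directly as fitted, not renormalized over
the truncated window.  For anisotropic tensors the closed-form relaxation
time from the three eigenvalues is provided (`tauFromTensor()`); estimating
the tensor itself from trajectories (quaternion-covariance fitting by
simulated annealing in the original workflow) is intentionally out of
scope, so the tensor route accepts eigenvalues as inputs.  The rotational
finite-size correction is $D_r = D_r^{PBC} + k_BT/(6\eta L^3)$, followed by
the same viscosity rescaling.

Apparent hydrodynamic radii invert the Stokes-Einstein relations
$D_t = k_BT/(6\pi\eta R_h)$ and $D_r = k_BT/(8\pi\eta R_h^3)$;
`stokesEinsteinRatio()` reports relative diffusion, relative fluidity and
their ratio, which equals one when the generalized Stokes-Einstein relation
$D(c)/D_0 = \eta_0/\eta(c)$ holds and falls below one when transient
clustering slows diffusion beyond the viscosity increase.

# Contacts, clusters and kinetics

Two molecules are in contact when any heavy-atom pair is strictly within
5 A under the minimum image; residue-level densities count crowder heavy
atoms strictly within 7 A of each C-alpha.  Strict `<` matches the "less
than" convention of the source protocol and is applied uniformly, since
boundary frames differ between conventions.  The search is the exact
all-pairs computation, vectorized per frame; at the molecule counts this
package targets (tens of molecules) a cell list would not change results
(exact agreement is required) and would not measurably change cost, so the
brute-force path is the implementation rather than a fallback.

The contact graph is decomposed into connected components per frame;
`clusterReport()` distinguishes direct partners (graph neighbors of a
probe) from in-cluster partners (co-members of its component).  Cluster
size *distributions* are deliberately not reported: with few molecules per
system they are not reliable.

Contact survival uses the intermittent autocorrelation
$P(\Delta t) \propto \sum_i \langle\delta_i(t)\delta_i(t+\Delta t)\rangle$
averaged over all pairs — including never-contacting pairs, as the
unconditional $1/N_p$ in the defining formula implies — over all sliding
origins (the printed index bounds of the source formula are garbled; the
standard origin-averaged estimator is used).  The curve is normalized by
$P(0)$ before fitting so the weights of the triple-exponential

$$P(\Delta t) \approx w_1 e^{-\Delta t/\tau_1} + w_2 e^{-\Delta t/\tau_2} +
(1-w_1-w_2)e^{-\Delta t/\tau_3}$$

are interpretable; the normalization and the fitted form are recorded in
metadata.  The fit keeps weights on the probability simplex via a softmax
parameterization, restarts from log-spaced time-constant triplets, orders
the constants, and flags degenerate solutions (collapsed constants) instead
of failing.  For a stationary contact process $P(\Delta t)$ decays to a
plateau (the mean contact probability), which a pure multi-exponential fit
absorbs into $\tau_3$; `contactACF(subtractPlateau = TRUE)` estimates the
plateau from the long-lag tail and renormalizes, which is the recommended
route when slow components matter.

Convergence is diagnosed by the windowed Z-score
$|a_{400} - a_{max}| / (\mathrm{SEM}(a_{400}) + \mathrm{SEM}(a_{max}))$
comparing a 400 ns short-time average with the remaining-trajectory
average; $Z \approx 1$ means agreement within one standard error.  The
source protocol does not define SEM for autocorrelated series; block
averaging with five blocks per interval is used, the standard unbiased
choice.

# Colloid-theory interpretation

Center-of-mass radial distribution functions are normalized by the
ideal-gas shell expectation in the periodic box.  The second virial
coefficient integrates $2\pi(1-g(r))r^2$ to a caller-supplied $r_{max}$
(the protocol chose the limit per pair, just past the first peak; no
automatic peak detection is attempted), with the unsampled hard-core region
below the first bin contributing analytically as $2\pi r_0^3/3$ — omitting
it would bias $B_2$ positive by the core volume.  The adhesive-hard-sphere
relation $B_2 = 4V_{HS} - V_{HS}/\tau_B$ yields the Baxter stickiness
$\tau_B$, with $V_{HS} = \tfrac{4}{3}\pi a^3$ for homotypic and
$\tfrac{2\pi}{12}(a_1+a_2)^3$ for heterotypic pairs, and
$K_D = \tau_B/V_{ref}$ converted to mM.  For probe-crowder pairs $V_{ref}$
is the probe's own sphere volume so that probe binding is comparable across
crowders; for crowder-crowder pairs it is the pair's $V_{HS}$.  This
resolution of the ambiguously printed defining relation was verified
numerically against all printed table rows.  Note that for weakly
interacting pairs ($B_2$ close to $4V_{HS}$) $\tau_B$ is sensitive to small
volume changes, so recomputing volumes from rounded radii can shift
$\tau_B$ by more than the printed precision; printed volumes are therefore
accepted as direct inputs.

Concentration dependence uses $c\,[\mathrm{g/L}] = 1430\,\phi$ as a fixed
configuration constant (the source fit does not state which concentration
column entered it; a clearly-labelled exploratory refit helper exists but no
pipeline stage refits it), the quadratic law
$\eta_r = 1 + 2.5\phi + b\phi^2$, the Mooney law
$\eta_r = e^{S\phi/(1-K\phi)}$ (with the pole $K\phi = 1$ kept outside the
data during optimization), the bridge $b = 5.931 + 1.899/\tau_B$, and the
effective-cluster diffusion models
$D(\phi) = D_0/(\eta_r(\phi)(1+\varsigma\phi)^{1/3})$ (translational) and
$D_0/(\eta_r(\phi)(1+\varsigma\phi))$ (rotational) with $\varsigma \ge 0$
enforced as a bound.

# Synthetic generators and what passing tests mean

Each generator draws from per-generator, per-particle sub-streams of a
master seed, so enlarging a system does not reshuffle existing particles,
and attaches a `GroundTruth` record.

* `genBrownian()`: independent Gaussian steps of variance $2D\,dt$ per
  dimension; wrapped and continuous paths both retained.
* `genRotational()`: a rigid site template rotated by composing small
  random rotations whose rotation vectors have component variance
  $2D_r\,dt$ — isotropic by construction, with
  $\langle P_2\rangle = e^{-6D_r t}$ in the small-step limit.
* `genOUPressure()`: exact AR(1) discretization of an Ornstein-Uhlenbeck
  process per tensor component, autocovariance $C_0 e^{-t/\tau_c}$, whose
  Green-Kubo integral $V C_0 \tau_c/(k_BT)$ is analytic.
* `genTelegraphContacts()`: discrete-time two-state Markov chains with
  per-step flip probabilities $k\,dt$ (first-order accurate; the exported
  closed-form oracle `telegraphContactACF()` uses the same discretization).
* `genConcentrationSeries()`: viscosity/diffusion tables from the quadratic
  or Mooney law with the cluster factor and multiplicative Gaussian noise.

These fixtures validate estimator correctness, not force-field realism:
there are no particle interactions, no hydrodynamic coupling, no protein
geometry, and contact events are independent across pairs.  A passing
recovery test demonstrates that the estimator chain is unbiased and
correctly scaled under its own model assumptions — it says nothing about
sampling problems real MD data can have (slow conformational degrees of
freedom, correlated replicas, non-exponential kinetics).

The default validation problem sizes were chosen once, as a balance between
statistical resolution and desk-scale runtime: 150 pressure trajectories of
20 000 samples (the trajectory count matching the published protocol's
ensemble size), 200 Brownian particles over 100 ns, rotational fixtures of
200-400 ns with 150 vectors (short rotational fixtures bias the harmonic
relaxation time upward, because tail noise buys the double-exponential a
spurious fast component), telegraph ensembles of 500 pairs over 2 400 ns,
and Mooney recovery on 15 volume fractions with 8 replicate measurements at
3% noise.  The telegraph study mixture (survival times 0.1/3/60 ns) uses
per-component on-rates proportional to the off-rates so that all three
ACF amplitudes are comparable — with a single shared on-rate, stationary
amplitudes scale as $w_i k_{on}/k_{off,i}$ and the fast component becomes
unrecoverable — and the slow component's time constant is tested with the
plateau-subtracting estimator for the reason given above.

# Known limitations

* Only cubic boxes and uniform time grids are supported.
* PDB/DCD input relies on `bio3d`; XTC is rejected (no installed reader)
  — convert to DCD or the package's columnar text fixture format.
* The Green-Kubo estimator inherits the small mean-removal bias discussed
  above; it is controlled by the weighted extrapolation but grows if
  $\tau_{max}$ approaches the trajectory length.
* Multi-exponential fits are intrinsically ill-conditioned; the multi-start
  machinery makes the reported optimum reproducible (fixed sub-seeds) but
  cannot make a flat residual surface informative.  Cross-pair spreads and
  the degeneracy flag should be consulted before interpreting individual
  time constants.
* Masses are not part of the data model; "centers of mass" are unweighted
  atom means.
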
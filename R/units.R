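## Internal unit system: lengths in Angstrom, times in ns (ps for the
## viscosity lag grid, converted at the module boundary), viscosities in cP,
## temperatures in K, pressures in bar, concentrations in g/L, number
## densities converted to mM at the colloid-module boundary.  All SI <->
## internal conversions live in this file so every physical formula is
## written once, in one unit convention.

#' Physical constants and unit conversions
#'
#' @description
#' `kBoltzmann` is the Boltzmann constant in J/K. `numberDensityToMillimolar`
#' converts a number density in particles per cubic Angstrom to a molar
#' concentration in mM (1 \eqn{\mbox{\AA}^{-3}} = 1.66054e6 mM).
#'
#' @format Length-one numeric constants.
#' @name constants
NULL

#' @rdname constants
#' @export
kBoltzmann <- 1.380649e-23

## 1 A^-3 of number density expressed in mM: 1e27 / (N_A per liter).
#' @rdname constants
#' @export
numberDensityToMillimolar <- 1.66054e6

## Product cP * A^2/ns * A equals 1e-24 Pa.s.m^2/s.m, so formulas of the
## Stokes-Einstein family written with eta in cP and lengths/times in A/ns
## need a single factor 1e24 applied to kB*T [J] to land on A^2/ns (or
## 1/ns, or A).  Derivation: 1 cP = 1e-3 Pa.s, 1 A^2/ns = 1e-11 m^2/s,
## 1 A = 1e-10 m.
.SI_TO_INTERNAL <- 1e24

## Green-Kubo prefactor: eta[cP] = 1e-29 * V[A^3] / (kB*T) * integral of
## ACF[bar^2] over tau[ps].  (1 A^3 = 1e-30 m^3, 1 bar^2 = 1e10 Pa^2,
## 1 ps = 1e-12 s, Pa.s -> cP is 1e3.)
.GK_PREFACTOR <- function(volume, temperature) {
  1e-29 * volume / (kBoltzmann * temperature)
}

.kT <- function(temperature) kBoltzmann * temperature
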
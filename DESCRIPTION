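Package: crowdedTransport
Title: Diffusion, Viscosity and Interaction Analysis for Crowded Protein Solutions
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Transport-coefficient estimators for molecular dynamics studies of
    crowded protein solutions. Computes Green-Kubo shear viscosities from
    pressure-tensor fluctuations with a multi-trajectory power-law/double-exponential
    extrapolation protocol, translational diffusion from mean-square displacements and
    rotational diffusion from second-Legendre orientation autocorrelations, both with
    analytic finite-size (periodic-box) corrections and water-model viscosity
    rescaling. Interprets protein-protein interactions through colloid theory: second
    virial coefficients from radial distribution functions, the Baxter sticky-sphere
    stickiness parameter, and dissociation constants, alongside Mooney and quadratic
    viscosity-concentration models and cluster-size-corrected diffusion fits. Includes
    contact detection, cluster decomposition, contact-survival kinetics and
    convergence diagnostics, plus seeded synthetic generators (Brownian, rigid-body
    rotational, Ornstein-Uhlenbeck pressure, telegraph contacts, concentration series)
    with recorded ground truth for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, minpack.lm, bio3d
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
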
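Package: npcable
Title: Finite-Element Simulation of Coupled Nernst-Planck Electrodiffusion
    and Cable-Equation Action Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional P1 Lagrange finite-element simulator for the
    electrical activity of a single cardiac cell, modelled as an elliptical
    domain in which six reacting ionic species move by Fickian diffusion and
    electromigration (Nernst-Planck transport) while the membrane potential
    obeys a modified cable equation driven by the net ionic current and an
    external stimulus. The reaction network is the suicide-substrate
    (mechanism-based enzyme inhibition) mass-action system. Time marching is
    an IMEX splitting: explicit second-order Runge-Kutta (Heun) for the
    potential and a backward-Euler Galerkin step with Picard iteration for
    the transport equations. Includes a deterministic ellipse mesher, Gmsh
    MSH v2.2 and legacy-VTK ASCII readers/writers, a well-mixed kinetics
    reference integrator, manufactured-solution convergence studies,
    time-step stability studies, and electrophysiological validation
    (excitability, all-or-none threshold, action-potential morphology).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
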
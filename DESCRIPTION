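Package: rdcell
Title: Hybrid Continuum-Discrete Simulation of Reaction-Diffusion Systems
    Coupled to Cell Agents
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finite-element simulation of arbitrary numbers of chemicals
    reacting and diffusing on a two-dimensional rectangular domain with
    subdomain-varying diffusion coefficients, coupled to point-like cell
    agents that run intracellular reaction networks and exchange chemicals
    with the bulk through transport and membrane reactions.  Models are
    specified through a plain-text model directory (domain topology,
    per-subdomain diffusion and boundary tables, and a one-reaction-per-line
    kinetics grammar).  Includes verification analytics: traveling-wave
    speed measurement against the Fisher-KPP analytic profile, L2
    convergence scoring, and Schnakenberg steady-state, Hopf and Turing
    linear stability analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
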
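Package: pkpdabm
Title: Agent-Based Pharmacokinetic and Pharmacodynamic Simulation of Drug
    Effects on 2D Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates systemic pharmacokinetics (one- and two-compartment
    models solved in closed form, or models supplied as SBML files), dosing
    schedules with loading doses and confluence-triggered first doses, drug
    diffusion and decay in a 2D voxelized microenvironment with vessel-like
    Dirichlet boundaries scaled by a Biot number, mass-conserving cellular
    uptake, intracellular damage accumulation with linear and constant repair,
    and Hill-type pharmacodynamic effects on proliferation, apoptosis,
    necrosis, and motility of off-lattice cell agents. Ships packaged sample
    experiments and a dose-sweep harness for IC50-style response curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Rcpp,
    stats,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
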
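Package: drnlha
Type: Package
Title: Mean-Field Firing-Rate Model of the Serotonin-Orexin DRN-LHA Circuit
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of a four-population mean-field
    firing-rate model of the dorsal raphe nucleus (serotonergic and GABAergic
    populations) coupled to the lateral hypothalamus (orexinergic and
    GABAergic populations).  Population input-output relations are
    threshold-linear; slow metabotropic receptor currents follow first-order
    kinetics while fast ionotropic GABAergic synapses are treated as
    instantaneous.  Provides analytic steady states with linear stability
    analysis, second-order Runge-Kutta simulation, steady-state parameter
    sweeps, localisation of the slow-oscillation (Hopf) boundary in the
    serotonin-to-hypothalamic-GABA coupling, phasic pulse-stimulation
    experiments under fast or slow receptor timescales, and orexin-knockout
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils, graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), deSolve, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
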
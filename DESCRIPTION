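Package: hybridsys
Title: Hybrid Dynamical Systems Simulation and Dominant-Scale Model Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, simulating and reducing hybrid dynamical
    systems models of the kind used for conductance-based neuron models.
    Provides interval, point-set and trajectory containers; a small symbolic
    expression language with exact differentiation; an adaptive Dormand-Prince
    5(4) integrator with dense output and arbitrary-precision zero-crossing
    event detection; a regime-graph hybrid simulator with guards and reset
    maps; model-interface wrappers with validation features and failure
    recovery; and a dominant-scale analysis toolbox that extracts epochs of
    constant dominant influence from a trajectory and assembles a reduced
    hybrid (differential-algebraic) model, demonstrated on the Hodgkin-Huxley
    action potential and integrate-and-fire fixtures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
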
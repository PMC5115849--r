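Package: taskcircuits
Title: Coupled RLC-Circuit Model of Task Allocation in Social Wasp Colonies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulator for task partitioning of nest construction in
    swarm-founding Metapolybia wasp colonies, modelled as four mutually
    coupled damped-oscillator (RLC) circuits: water foragers, the communal
    "common stomach" water store, pulp foragers, and builders. Provides the
    coupled second-order model with two coupling interpretations
    (second-derivative and charge-equivalence), closed-form equilibria and a
    single-circuit analytic oracle, a fixed-step RK4/Euler integrator with
    timed parameter-change events, a registry of perturbation experiments
    with pre/post equilibrium reports, phase-plane attractor diagnostics,
    YAML configuration, CSV/JSON serialization, and a command-line entry
    point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
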
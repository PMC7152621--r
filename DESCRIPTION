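Package: stemgame
Title: Evolutionary Game Dynamics of Stem-Cell Therapy Against Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the competition between cancerous and healthy cells as a
    two-strategy evolutionary game and analyzes the effect of stem-cell
    injection therapy on its replicator dynamics. Provides closed-form
    equilibrium computation with stability classification for the baseline and
    therapy-augmented systems, a case taxonomy of the reduced parameter space,
    numerical integration of trajectories with convergence detection, therapy
    design (choice of the composite control parameter and of the injection
    parameters) including steady-state sweeps and reproduction of reference
    equilibrium values, and a command-line interface with JSON/YAML
    configuration and CSV/JSON outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
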
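Package: hospitalflow
Title: Dynamic Nonlinear Flow Modelling of Patient Flow Through a
    Hospital Network
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models patient flow through a hospital as a dynamic
    single-commodity network flow problem. Wards are vertices with bed
    capacities, staff (server) counts and length-of-stay distributions;
    care pathways are edges with waiting-queue capacities and routing
    (distribution) probabilities. At each arrival-rate step the per-ward
    traffic intensity adjusts vertex and edge capacities into a static
    residual graph, augmenting paths are found by depth-first search over
    strictly positive residuals, and forward-only flow is pushed (no
    backward residual edges, since patients do not take alternative care
    pathways). The run accumulates a dynamic residual graph (per-edge
    min/max residual) and per-ward residual time series, from which
    bottleneck persistency, severity, overflow, blockage colouring and
    k-hop root-cause traces are derived. Includes a synthetic hospital
    generator and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
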
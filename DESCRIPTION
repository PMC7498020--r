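Package: streamprep
Title: Prepare Spatial Stream-Network Data from Digital Elevation Models
Version: 0.1.0
Authors@R: person("streamprep", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives topologically valid stream networks from a digital
    elevation model (D8 and multiple-flow-direction routing, priority-flood
    depression filling, optional stream burning), corrects complex
    confluences, delineates reach contributing areas and catchments, snaps
    observation sites to the network, generates evenly spaced prediction
    sites, summarises predictor layers over reach contributing areas and
    catchments (approximate and exact site attribution), and exports a
    '.ssn' directory (edges, sites, prediction sites, per-network topology
    tables) ready for spatial stream-network modelling. Self-contained: no
    external GIS is required, and a deterministic synthetic-terrain
    generator supports fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
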
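Package: vaspol
Title: Vascular Network Hemodynamics and Endothelial Polarity Analysis
Version: 0.1.0
Authors@R: person("PolNet", "Reimplementation", email = "dev@example.org", role = c("aut", "cre"))
Description: Converts a binary vessel-lumen mask into a radius-annotated
    vascular graph, computes network hemodynamics (pressure, flow, velocity,
    wall shear rate and oriented wall shear stress vectors) under pressure
    boundary conditions with shear-thinning blood rheology, and quantifies
    endothelial-cell polarity (nucleus-to-Golgi vectors) against local flow:
    directionality tables, polar histograms with Kuiper tests, a WSS
    sensor-threshold analysis and scalar-product slope regression. Includes
    a synthetic-fixture generator (tubes, crossings, vein-artery-vein
    plexuses, cells with von Mises polarity coupled to local WSS) so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
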
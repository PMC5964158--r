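Package: repe
Title: Regional Personalized Electrodes for Transcranial Electrical Stimulation
Version: 0.1.0
Authors@R:
    person("RePE", "Maintainers", email = "repe-dev@example.org", role = c("aut", "cre"))
Description: Tools to shape, position and evaluate regional personalized
    electrodes (RePE) for transcranial electrical stimulation. Builds a
    printable electrode outline from the scalp projection of an individual
    central sulcus, computes scalp-landmark distances for
    neuronavigation-free (re)positioning, quantifies positioning error
    (nearest-point distances, intraclass correlation, repeated-measures
    ANOVA), and evaluates electrode montages with a quasi-static
    volume-conductor field solver on a labeled voxel grid. Ships a
    synthetic head-phantom generator with known ground truth so the whole
    pipeline is testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    FNN,
    jsonlite,
    yaml,
    xml2,
    optparse,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
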
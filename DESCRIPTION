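Package: neuroarbor
Title: Morphometry, 3D Sholl Analysis and Stereological Density Estimation
    for Traced Neuron Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing digitally traced pyramidal-neuron dendritic
    arbors. Reads SWC and Amira SpatialGraph ASCII reconstructions into a
    validated rooted-tree container, computes per-neuron morphometrics (total
    dendritic length, terminal-dendrite count, spatial volume), exact
    three-dimensional Sholl intersection profiles on concentric spheres
    centred at the soma, and stereological neuron-density estimates from
    marker centroids counted in systematically placed blocks. Includes
    two-group statistics (mean +/- SEM, Student or Welch t-tests, per-shell
    and range-wise Sholl comparisons), a seeded stochastic generator of
    synthetic neuron cohorts with planted between-group effects for
    validation, and an end-to-end analysis pipeline with CSV/JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
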
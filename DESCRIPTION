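Package: SynapseCorr
Title: Correlative Synapse Structure-Function Analysis from Live Imaging and 3D
    Single-Molecule Localisation Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for correlating presynaptic function with nanoscale protein
    organisation at individual synapses. Quantifies stimulus-evoked calcium
    influx and vesicle release from dual-reporter (pHluorin/red calcium
    indicator) time-lapse movies; processes 3D single-molecule localisation
    tables by spectral demixing of two-camera photon ratios, lateral drift
    correction by cross-correlation, and super-resolved rendering; segments
    nanoscale clusters and subsynaptic domains from localisation point clouds
    by Voronoi density analysis; registers the two imaging modalities with a
    landmark affine transform; and reports per-synapse structure-function
    correlation statistics. Includes a synthetic-data generator with ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    mclust,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'clusters.R'
    'config.R'
    'io.R'
    'registration.R'
    'simulate.R'
    'smlm.R'
    'stats.R'
    'traces.R'
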
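Package: voxgraph
Title: Voxel-Level Graph Analysis of ROI-Restricted Resting-State Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds voxel-wise correlation graphs from region-of-interest
    resting-state BOLD time series and characterizes their functional
    architecture. Provides nuisance regression, prewhitening and zero-phase
    band-pass preprocessing; adaptive percolation thresholding of
    synchronization matrices with a common group threshold; nodal and global
    network metrics (degree, clustering coefficient, characteristic path
    length) normalized against degree-preserving rewired null ensembles;
    within-mask smoothed metric maps and hub extraction; and group-level
    inference with repeated-measures interaction maps, paired contrasts,
    Monte-Carlo cluster correction and baseline-dependence regression. A
    synthetic band-limited BOLD generator with plantable connectivity effects
    makes every stage verifiable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    Matrix
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
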
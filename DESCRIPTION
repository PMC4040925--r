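Package: fccsnet
Title: Fluorescence Cross-Correlation Spectroscopy Analysis and
    Protein-Complex Network Inference
Version: 0.1.0
Authors@R:
    person("fccsnet", "maintainers", email = "maintainer@fccsnet.org",
           role = c("aut", "cre"))
Description: Quantitative workflow for detecting pre-assembled protein
    complexes in the cytosol from two-color fluorescence cross-correlation
    spectroscopy (FCCS): multi-tau correlation of photon-count traces,
    confocal effective-volume calibration from dye references, apparent
    association constants corrected for dark red-fluorophore fractions,
    robust association scores, FRAP recovery-kinetics fitting, exact
    nonparametric cohort statistics, and network-level inference of ternary
    complexes and mutually exclusive interactions.  Includes a
    Brownian-dynamics photon-trace simulator so the full pipeline is
    testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
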
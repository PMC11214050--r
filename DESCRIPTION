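Package: nucleoclust
Title: Physical Simulation of Nucleosome Clustering in Euchromatin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-stage physical simulator of euchromatin organization driven
    by cooperative HP1 binding to H3K9me3-marked nucleosome arrays. Provides a
    grand-canonical transfer-matrix model of HP1 binding thermodynamics on 1D
    nucleosome arrays, heat-bath Monte Carlo sampling of DNA linker lengths
    from the interaction-modulated exponential distribution, base-pair-resolved
    construction of 3D chromatin fibers under a kinked twistable wormlike chain
    model, Metropolis relaxation of nucleosome sterics with a shifted
    Lennard-Jones repulsion, and nucleosome cluster detection with
    projected-inertia size statistics. Includes synthetic generation of
    exponentially correlated epigenetic mark patterns, a pipeline runner, and
    parameter-sweep experiment presets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
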
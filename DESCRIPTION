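Package: mscorval
Title: Structural-Correlation Validation of Multi-State NMR Protein Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Validation and optimization of multi-state NMR protein
    structures via structural correlations. Conformational states of the
    members of a structure bundle are identified residue by residue through
    Gaussian-mixture clustering of interresidual distances; the pairwise
    adjusted mutual information of these residue-specific clusterings forms
    a correlation matrix whose average, the structural correlation parameter
    mu, quantifies how cleanly the bundle separates into states. The package
    also provides the CYANA-style distance-restraint target function with
    r^-6 ensemble averaging, a coarse-grained multi-state restraint
    minimizer, a synthetic multi-state ensemble generator, and validation
    assays (state-number scan, population scan, restraint titration,
    leave-one-out restraint ranking, distance-range profiling, convergence
    scan).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    grDevices,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
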
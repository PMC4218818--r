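Package: plaquemech
Title: Lesion-Specific Vessel Wall Mechanics and Inflammation Mapping from Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking the composition of atherosclerotic vessel
    cross-sections to their intramural mechanics and to spatial maps of
    immunohistochemical marker positivity. The package segments stained
    histology images into tissue classes (fibrous, cellular, lipid/necrotic,
    calcified), builds lesion-specific two-dimensional plane-strain finite
    element models with rule-of-mixtures material properties, removes
    fixation artifacts by an iterative pre-inflation procedure, computes Von
    Mises stress and strain excursion fields (relative to the lesion
    median), and tests the association between excursion and marker
    positivity with baseline/tertile/decile histogram statistics. A
    synthetic phantom generator provides fully specified test specimens so
    the entire pipeline is reproducible without tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    png,
    yaml,
    stats,
    grDevices,
    graphics,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
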
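Package: brachymc
Title: Monte Carlo Photon Dosimetry for Brachytherapy Seeds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained photon Monte Carlo engine and TG-43 dosimetry
    toolkit for low-, high- and pulsed-dose-rate brachytherapy sources.
    Parametric models of six commercial seeds are transported with analytic
    ray tracing inside the source and Woodcock delta tracking in voxel
    phantoms, under the kerma approximation with track-length-estimator
    (TLE) scoring.  The package extracts the TG-43 quantities (dose rate
    constant, radial dose function, anisotropy function) from annular kerma
    maps and vacuum air-kerma-strength scoring, generates and replays
    phase-space files, and evaluates multi-seed treatment plans in
    heterogeneous CT-derived phantoms (HU-to-material conversion, cumulative
    dose-volume histograms, isodose masks, dose-map comparisons).  Photon
    interaction data are embedded as plain-text element tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
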
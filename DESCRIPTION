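Package: apatitepdf
Title: Real-Space Pair Distribution Function Analysis of Nanocrystalline
    Hydroxyapatite
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Small-box (real-space) refinement of X-ray pair distribution
    function data for nanocrystalline and carbonate-substituted
    hydroxyapatite.  Builds an ordered P1 apatite cell from rigid-body
    phosphate parameterisations, computes model G(r) curves with nanosheet
    shape damping and r-dependent correlated-motion temperature factors,
    refines structural parameters by bounded nonlinear least squares, and
    provides charge-balanced composition and occupancy prediction from
    carbonate content, Scherrer coherence lengths from single-peak fits,
    FT-IR carbonate quantification, correlation reporting across sample
    cohorts, and synthetic-data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
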
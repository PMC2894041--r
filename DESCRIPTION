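Package: hicfmap
Title: Simulation and Assembly of HICF BAC Physical Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates bacterial artificial chromosome (BAC) libraries and
    high-information-content fingerprinting (HICF) with multi-enzyme
    digestion and color labeling, assembles restriction fingerprints into
    contigs by tolerance band matching and Sulston-score clustering with an
    FPC-style iterated merge schedule (DQer, End-to-End, Singles-to-End),
    screens three-dimensional clone pools by simulated PCR to anchor
    genetic markers, and integrates the resulting physical and genetic
    maps, reporting the standard physical-map summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
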
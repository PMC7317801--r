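Package: wolfdemog
Title: Spatially Explicit Coalescent Inference of Grey Wolf Demography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structured-coalescent simulation and Approximate Bayesian
    Computation for the Late Pleistocene demography of Northern Hemisphere
    grey wolves. Models the wolf range as seven demes connected by gene
    flow, simulates genealogies of dated (ancient and modern) mitochondrial
    samples under static, bottleneck, range-expansion and combined
    scenarios (16 in total), and selects among them with ABC on pairwise
    TMRCA summary statistics. Also provides isolation-by-distance (Mantel)
    and AMOVA population-structure analyses, and a synthetic-data generator
    producing dated genealogies and mitogenome-like alignments with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
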
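Package: panfill
Title: Neural-Network Reaction Imputation and Weighted Gap-Filling of
    Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns reaction co-occurrence patterns across bacterial
    pan-reactomes with a fully connected neural network trained under a
    masked, class-weighted binary cross-entropy loss, and uses the
    resulting per-reaction presence scores as costs in a half-interval
    linear-programming gap-filler that completes genome-scale metabolic
    models until they carry biomass flux. Includes readers for
    ModelSEED-dialect reaction tables, BiGG-dialect JSON databases, SBML
    Level 3 and COBRA JSON models, quality-based genome selection and
    train/test splitting of reaction incidence matrices, corruption
    schemes for simulating incomplete genomes, evaluation metrics
    (confusion counts, F1, balanced accuracy, frequency-binned recall,
    Jaccard nearest-neighbour distances, reaction essentiality, carbon
    utilisation profiles), and generators for clade-structured synthetic
    benchmark worlds with a mass-balanced toy biochemistry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    boot,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
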
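Package: atrophynet
Title: Connectome-Based Spreading Analysis of Neurodegenerative Atrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how neurodegenerative atrophy is shaped by
    brain network architecture. Implements normative w-score atrophy maps
    from morphometry cohorts, connectome-based disease exposure and
    node-neighbour correlation, epicenter inference by dual ranking and by
    an agent-based susceptible-infected-removed (SIR) propagation model,
    spatial-autocorrelation-preserving spin tests and degree- and
    edge-length-preserving network rewiring nulls, behavioural partial
    least squares with permutation, bootstrap, and split-half
    cross-validation, ensemble-null gene-category enrichment, and patient
    subtype contrasts. A synthetic-data module generates spatially embedded
    connectomes, planted spreading atrophy, voxel-level cohorts, clinical
    tables with a planted latent factor, and spatially autocorrelated gene
    expression, so that every stage of the pipeline can be exercised against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
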
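Package: hic3d
Title: Restraint-Based 3D Chromatin Modeling from Hi-C Contact Matrices
Version: 0.1.0
Authors@R:
    person("hic3d", "developers", email = "hic3d@example.org", role = c("aut", "cre"))
Description: Reconstructs coarse-grained 3D chromatin conformation ensembles
    from per-chromosome Hi-C contact matrices by converting contact
    frequencies to pairwise distance restraints (power-law scaling plus
    log-log interpolation of the empirical contact decay) and optimizing
    bead-spring polymer models against them. Includes downstream structural
    analyses: regeneration of a modeled Hi-C matrix by inverse mapping,
    A/B compartment calling via observed/expected normalization and spectral
    clustering, per-bin degree-of-compartmentalization profiles, mapping of
    genome tracks onto structures, RMSD clustering of ensembles, and a
    two-type chromatin-domain classifier built on log-variance contact
    features with k-means seeding and linear discriminant analysis. A
    synthetic-data module generates ground-truth structures, plaid
    compartment matrices, and two-type domain cohorts so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    rtracklayer,
    GenomicRanges,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
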
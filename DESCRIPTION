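Package: ripscreen
Title: Consensus Docking and QSAR Virtual Screening for RIPK1 Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual-screening pipeline for receptor-interacting protein
    kinase 1 (RIPK1) inhibitor discovery that combines docking-derived
    protein-ligand interaction fingerprints (PLIFs) with machine learning.
    Builds robust per-residue interaction fingerprints from docking poses,
    mines residue-contact signatures enriched in actives, filters screening
    libraries by PLIF similarity to a reference ligand, trains an ensemble
    random-forest QSAR classifier with a reliability-density applicability
    domain, and selects consensus hits with maximum-common-substructure
    based applicability and chemical-novelty analysis. Includes a seeded
    synthetic-data generator with planted residue-contact structure so the
    whole funnel can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    ChemmineOB,
    ranger,
    igraph,
    bio3d,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
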
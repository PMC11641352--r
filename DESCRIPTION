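Package: tgvscreen
Title: Fingerprint Clustering and Network Pharmacology Toolkit for
    Herbal Compound Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Virtual-screening toolkit for herbal compound libraries built
    around three-dimensional hierarchical fingerprint clustering with
    Tanimoto representative selection. Computes binary molecular
    fingerprints (166-key MACCS or 2048-bit hashed topological paths) from
    SMILES libraries, embeds them into three dimensions with t-SNE,
    clusters the embedding agglomeratively, and picks each cluster's
    Tanimoto medoid as its representative compound. A network-pharmacology
    stage merges scored disease-gene sources, intersects them with
    compound target maps, ranks molecules by target overlap, ranks hub
    genes by degree in a protein-protein interaction network, and runs
    hypergeometric gene-set enrichment with Benjamini-Hochberg correction.
    An energetics stage screens docking score tables for the best
    molecule-target combination, aggregates MM/PBSA per-snapshot energy
    components, and computes hydrogen-bond occupancy statistics from
    trajectory frame records. Seeded synthetic generators emulate every
    input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
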
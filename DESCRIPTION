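Package: microMEN
Title: Molecular Ecological Network Analysis of Microbiome Count Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building and interrogating molecular ecological
    networks (MENs) from 16S rRNA OTU count tables. Implements SparCC
    compositional correlation estimation with Dirichlet resampling and
    iterative strong-pair exclusion, pooled permutation significance with
    Benjamini-Hochberg control, random-matrix-theory (RMT) selection of the
    correlation cut-off from the eigenvalue nearest-neighbour spacing
    distribution, signed co-occurrence network construction, a full suite of
    topological indices with Maslov-Sneppen degree-preserving null ensembles,
    Clauset-Newman-Moore greedy modularity, Zi-Pi keystone-taxon
    classification, and module eigengene correlation with sample covariates
    such as blood heavy-metal concentrations. Includes alpha/beta diversity,
    PCoA, ANOSIM and rank-sum group comparisons, and a synthetic-data
    generator that plants known correlation modules, group effects and
    covariate couplings so every stage has a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    vegan,
    ape,
    MASS,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    phyloseq,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Microbiome, Network, GraphAndNetwork, Metagenomics, Software
RoxygenNote: 7.3.3
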
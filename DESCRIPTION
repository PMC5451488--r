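Package: aridnet
Title: Aridity-Gradient Soil Microbiome Diversity and Co-Occurrence Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for analysing soil microbiome composition
    along aridity gradients from OTU count tables, rooted phylogenies,
    taxonomy assignments and soil-climate metadata.  Implements phylogenetic
    alpha diversity (Faith's PD, Shannon, Simpson) and rarefaction, weighted
    and unweighted UniFrac beta diversity with principal-coordinate
    ordination, Mantel/ANOSIM permutation tests and exhaustive BEST/BioEnv
    environmental-driver selection, Spearman co-occurrence network inference
    with Benjamini-Hochberg false-discovery control, network deconvolution
    of transitive correlations and random-matrix-theory correlation
    thresholding, aridity-class subnetwork topology comparison, a
    richness-matched resampling null model, and taxon-abundance gradient
    reports.  Ships a synthetic aridity-gradient community generator with
    planted co-occurrence modules so the whole pipeline is testable without
    access to field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
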
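Package: seabiome
Title: Biogeography and Neutral Assembly Analysis of Marine Bacterioplankton
    Communities
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for open-ocean 16S rRNA OTU surveys:
    contaminant screening against a negative control, single rarefaction,
    alpha-diversity (observed OTUs, Shannon, Chao1, Heip's evenness) with
    rank-based group tests and least-squares regression, weighted UniFrac and
    Bray-Curtis beta-diversity with PCoA, PERMANOVA, PERMDISP, ANOSIM and
    two-way SIMPER, distance-decay of community similarity, PCNM spatial
    eigenfunctions, partial distance-based redundancy analysis with forward
    selection by adjusted R-squared, variation partitioning with proportional
    apportioning, and Sloan neutral community model fitting. Includes a
    synthetic-community generator (Dirichlet-multinomial neutral assembly,
    Gaussian niche filtering, dispersal limitation) so every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    vegan,
    geosphere,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
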
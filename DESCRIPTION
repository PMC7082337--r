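Package: mnAOM
Title: Geochemical Mass Balance, Thermodynamics, and Multiheme Cytochrome
    Analysis for Manganese-Dependent Anaerobic Methane Oxidation
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing bioreactor enrichments performing anaerobic
    oxidation of methane (AOM) coupled to Mn(IV) oxide reduction. Provides
    gas/liquid methane partitioning via Henry's law, least-squares rate
    estimation and Mn(II) pool accounting from reactor time series,
    electron-balance stoichiometry and in-situ Gibbs free energy for balanced
    redox reactions, a multiheme c-type cytochrome (MHC) screen based on
    CXXCH heme-binding motifs with localization, S-layer-fusion and
    gene-cluster-context classification, transcripts-per-million (TPM)
    expression quantification with per-genome median thresholds, and
    comparative genomics via reciprocal-best-hit orthology, average amino
    acid identity (AAI), MHC ortholog families and Ward hierarchical
    clustering. Includes deterministic synthetic-data generators with ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph,
    ape,
    jsonlite,
    yaml,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Metagenomics, Microbiome, Transcriptomics, ComparativeGenomics
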
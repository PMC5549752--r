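Package: cloudAmplicon
Title: Paired DNA/RNA Amplicon Analysis of Cloud Water Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream analysis of paired DNA/RNA (rDNA/rRNA)
    amplicon surveys of low-biomass aerial habitats such as cloud water: FASTQ
    read cleaning (length, primer, ambiguity and quality rules), reference
    greedy centroid OTU clustering at a configurable identity threshold,
    conservative community filtering (minimum-read artefact removal,
    negative-control decontamination, phantom-OTU removal), closed-form
    diversity and evenness statistics (Shannon H, ACE richness, Gini and
    Lorenz curves, exact and subsampled rarefaction), RNA:DNA activity ratios
    with banding and top-taxon selection, between-sample comparisons
    (shared-OTU partitions, Bray-Curtis similarity, cells-per-air-volume
    conversion), and a seeded synthetic-community generator with full ground
    truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment,
    vegan,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'otu-experiment.R'
    'io.R'
    'qc.R'
    'clustering.R'
    'filters.R'
    'diversity.R'
    'activity.R'
    'comparison.R'
    'synthetic.R'
    'reference-data.R'
    'pipeline.R'
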